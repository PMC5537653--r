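#' Detect the attL/attR direct repeat of a prophage region
#'
#' Site-specifically integrated prophages are flanked by a direct repeat:
#' the attL/attR common core, observed as the first N nucleotides of the
#' prophage region recurring just downstream of the region end. This
#' scans for the longest L <= `max_prefix` such that the region's L-nt
#' prefix occurs exactly (forward strand) within `window` bp downstream of
#' the region end. Multiple downstream positions tying at the maximal L
#' resolve to the one nearest the region end.
#'
#' @param replicon Replicon nucleotide sequence (character string).
#' @param region_start,region_end 1-based inclusive prophage region bounds.
#' @param max_prefix Longest prefix length considered, bp.
#' @param window Downstream search window, bp (truncated with a warning at
#'   the replicon end).
#' @param min_len Minimum repeat length reported; best matches shorter than
#'   this return `NULL`.
#' @return A one-row data.frame (`repeat_length`, `attL_start`, `attL_end`,
#'   `attR_start`, `attR_end`, `repeat_sequence`, `anchor_trna` = `NA`), or
#'   `NULL` when no repeat of at least `min_len` is found. `attL_start`
#'   always equals `region_start` (prefix-anchored search).
#' @export
find_att_repeat <- function(replicon, region_start, region_end,
                            max_prefix = 200L, window = 1000L,
                            min_len = 10L) {
  n <- nchar(replicon)
  stopifnot(region_start >= 1, region_end <= n, region_start < region_end)
  region_len <- region_end - region_start + 1L
  if (region_len < min_len)
    stop("degenerate region: shorter than min_len")
  max_prefix <- min(max_prefix, region_len)
  if (region_end + window > n) {
    warning("search window truncated at replicon end")
    window <- n - region_end
  }
  if (window < 1) return(NULL)
  seq_raw <- charToRaw(replicon)
  prefix_raw <- seq_raw[region_start:(region_start + max_prefix - 1L)]
  best_len <- 0L
  best_pos <- NA_integer_
  for (pos in (region_end + 1L):(region_end + window)) {
    len <- match_len_at(seq_raw, prefix_raw, pos)
    if (len > best_len) {  # strict: nearest position wins ties
      best_len <- len
      best_pos <- pos
    }
  }
  if (best_len < min_len) return(NULL)
  data.frame(repeat_length = best_len,
             attL_start = region_start,
             attL_end = region_start + best_len - 1L,
             attR_start = best_pos,
             attR_end = best_pos + best_len - 1L,
             repeat_sequence = substr(replicon, region_start,
                                      region_start + best_len - 1L),
             anchor_trna = NA_character_,
             stringsAsFactors = FALSE)
}

#' Check tRNA reconstitution at a detected attachment site
#'
#' tRNA-anchored integration reconstitutes an intact tRNA gene at one
#' junction, so a genuine att site overlaps a tRNA feature. Returns `TRUE`
#' iff some tRNA feature overlaps the attL or attR interval by at least
#' 1 bp; the overlapping tRNA's id (or isotype) is recorded in the
#' returned site's `anchor_trna` field.
#'
#' @param att Att-site row from [find_att_repeat()].
#' @param features Feature data.frame including tRNA rows.
#' @return A list: `reconstituted` (logical) and `att` (the site with
#'   `anchor_trna` filled when reconstituted).
#' @export
check_trna_reconstitution <- function(att, features) {
  stopifnot(!is.null(att))
  trna <- features[features$kind == "tRNA", , drop = FALSE]
  overlaps <- function(s1, e1, s2, e2) s1 <= e2 & e1 >= s2
  hit <- overlaps(trna$start, trna$end, att$attL_start, att$attL_end) |
    overlaps(trna$start, trna$end, att$attR_start, att$attR_end)
  if (any(hit)) {
    anchor <- trna[which(hit)[1], ]
    att$anchor_trna <- if (!is.na(anchor$trna_isotype))
      anchor$trna_isotype else anchor$protein_id
    list(reconstituted = TRUE, att = att)
  } else {
    list(reconstituted = FALSE, att = att)
  }
}
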