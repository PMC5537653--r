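#' Length of a 1-based inclusive genomic region
#'
#' @param start,end 1-based inclusive coordinates (vectorized).
#' @return `end - start + 1`.
#' @examples
#' region_length(2834796, 2878945)  # 44150
#' @export
region_length <- function(start, end) {
  if (any(start > end)) stop("start greater than end")
  end - start + 1
}

#' GC content of a nucleotide sequence
#'
#' `100 * (G + C) / (A + C + G + T)`; N (and other IUPAC ambiguity codes)
#' are excluded from the denominator. Returned unrounded; display
#' convention elsewhere is two decimals, half-up.
#'
#' @param sequence Nucleotide string (A/C/G/T/N, case-insensitive).
#' @return GC percent, or `NA` (with a warning) for a sequence with no
#'   unambiguous bases.
#' @export
gc_content <- function(sequence) {
  counts <- table(strsplit(toupper(sequence), "")[[1]])
  acgt <- sum(counts[intersect(names(counts), c("A", "C", "G", "T"))])
  if (acgt == 0) {
    warning("no unambiguous bases; GC content undefined")
    return(NA_real_)
  }
  gc <- sum(counts[intersect(names(counts), c("G", "C"))])
  100 * gc / acgt
}

#' Gene count and coding density of a region
#'
#' Coding density is the fraction of the region covered by the union of
#' its CDS spans (overlapping CDS counted once), as a percentage.
#'
#' @param features Feature data.frame; only `kind == "CDS"` rows within
#'   the region are used (spans are clipped to the region).
#' @param region_start,region_end 1-based inclusive region bounds.
#' @return A list: `n_genes`, `coding_density_pct`.
#' @export
coding_stats <- function(features, region_start, region_end) {
  cds <- features[features$kind == "CDS" &
                    features$end >= region_start &
                    features$start <= region_end, , drop = FALSE]
  if (nrow(cds) == 0)
    return(list(n_genes = 0L, coding_density_pct = 0))
  starts <- pmax(cds$start, region_start)
  ends <- pmin(cds$end, region_end)
  covered <- sum(IRanges::width(IRanges::reduce(IRanges::IRanges(starts, ends))))
  list(n_genes = nrow(cds),
       coding_density_pct = 100 * covered / (region_end - region_start + 1))
}

#' Per-prophage summary row
#'
#' Assembles the standard comparative-table entry for one prophage region:
#' coordinates, inclusive size, gene count, GC content (two decimals,
#' half-up) and integration site.
#'
#' @param name Prophage name.
#' @param host Host strain label.
#' @param accession Replicon accession or identifier.
#' @param region_start,region_end Region bounds, 1-based inclusive.
#' @param sequence Replicon sequence (for GC of the region); `NA` to skip.
#' @param features Feature data.frame (for the gene count); `NULL` to skip.
#' @param integration_site Integration-site descriptor (e.g. a tRNA
#'   isotype) or `NA`.
#' @return A one-row data.frame mirroring the comparative-table columns.
#' @export
prophage_summary_row <- function(name, host, accession, region_start,
                                 region_end, sequence = NA,
                                 features = NULL,
                                 integration_site = NA_character_) {
  gc <- if (is.character(sequence) && !is.na(sequence))
    round_half_up(gc_content(substr(sequence, region_start, region_end)), 2)
  else NA_real_
  n_genes <- if (!is.null(features))
    coding_stats(features, region_start, region_end)$n_genes
  else NA_integer_
  data.frame(name = name, host = host, accession = accession,
             coordinates = sprintf("%d..%d", region_start, region_end),
             size_bp = region_length(region_start, region_end),
             n_genes = n_genes, integration_site = integration_site,
             gc_pct = gc, stringsAsFactors = FALSE)
}
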