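#' Scoring scheme for protein local alignment
#'
#' Bundles the substitution matrix, affine gap penalties and Karlin-Altschul
#' parameters used by [local_align()] and [all_vs_all()]. Defaults mirror
#' gapped BLASTP: BLOSUM62 with gap existence 11 and extension 1 (a gap of
#' length L costs `gap_open + L * gap_extend`), and the standard gapped
#' Karlin-Altschul constants lambda = 0.267 nats, K = 0.041.
#'
#' @param matrix A symmetric integer substitution matrix with amino-acid
#'   row/column names, or the name of a matrix shipped with Biostrings
#'   (e.g. `"BLOSUM62"`, `"BLOSUM45"`, `"PAM250"`).
#' @param gap_open Positive integer gap-existence penalty.
#' @param gap_extend Positive integer per-residue gap-extension penalty;
#'   must not exceed `gap_open`.
#' @param lambda,K Karlin-Altschul parameters (nats) used for bit scores and
#'   E-values. Absolute E-values will differ from NCBI BLAST, which applies
#'   composition-based statistics and edge-effect corrections.
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(matrix = "BLOSUM62", gap_open = 11L,
                           gap_extend = 1L, lambda = 0.267, K = 0.041) {
  if (is.character(matrix)) {
    name <- matrix
    env <- new.env()
    utils::data(list = name, package = "Biostrings", envir = env)
    matrix <- get(name, envir = env)
  } else {
    name <- "custom"
  }
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "integer"
  if (is.null(rownames(matrix)) || !identical(rownames(matrix), colnames(matrix)))
    stop("substitution matrix must have identical row and column names")
  if (!isTRUE(all.equal(matrix, t(matrix))))
    stop("substitution matrix must be symmetric")
  if (gap_extend > gap_open)
    stop("gap_extend must not exceed gap_open")
  if (gap_open <= 0 || gap_extend <= 0)
    stop("gap penalties must be positive")
  structure(
    list(matrix = matrix, matrix_name = name,
         gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend),
         lambda = lambda, K = K),
    class = "scoring_scheme"
  )
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat(sprintf("<scoring_scheme> %s, gap %d/%d, lambda %.3f, K %.3f\n",
              x$matrix_name, x$gap_open, x$gap_extend, x$lambda, x$K))
  invisible(x)
}

# Encode an amino-acid string as 0-based indices into the scoring matrix,
# erroring with the offending position for characters outside the alphabet.
encode_sequence <- function(sequence, alphabet, what = "sequence") {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  idx <- match(chars, alphabet)
  if (anyNA(idx)) {
    pos <- which(is.na(idx))[1]
    stop(sprintf("invalid character '%s' at position %d of %s",
                 chars[pos], pos, what))
  }
  idx - 1L
}

karlin_altschul <- function(raw_score, m, n, scoring) {
  bit <- (scoring$lambda * raw_score - log(scoring$K)) / log(2)
  list(bit_score = bit, evalue = m * n * 2^(-bit))
}

#' Optimal local alignment of two protein sequences
#'
#' Smith-Waterman local alignment with affine gaps. Percent identity uses
#' the BLAST `pident` convention (identical residue pairs over alignment
#' columns, gap columns included); query coverage is the aligned query span
#' over the query length (single best local trace, not summed HSPs). Among
#' co-optimal traces the one with the smallest (q_start, s_start), then the
#' smallest (q_end, s_end), is reported.
#'
#' When no residue pair scores positively (e.g. disjoint alphabets) the raw
#' score is 0, the alignment bounds are `NA` and identity/coverage are 0;
#' such hits can never satisfy network edge thresholds.
#'
#' @param query,subject Amino-acid strings (alphabet of the scoring matrix;
#'   X is allowed under BLOSUM62).
#' @param scoring A [scoring_scheme()].
#' @param query_id,subject_id Optional ids carried into the result.
#' @param db_residues Effective subject search-space size for the E-value;
#'   defaults to the subject length (pairwise m*n search space).
#' @return A one-row data.frame (a similarity hit): `query_id`, `subject_id`,
#'   `raw_score`, `bit_score`, `evalue`, `identity_pct`,
#'   `query_coverage_pct`, `q_start`, `q_end`, `s_start`, `s_end`.
#' @examples
#' local_align("HEAGAWGHEE", "PAWHEAE")$raw_score
#' @export
local_align <- function(query, subject, scoring = scoring_scheme(),
                        query_id = "query", subject_id = "subject",
                        db_residues = NULL) {
  if (!nzchar(query) || !nzchar(subject))
    stop("sequences must be non-empty")
  alphabet <- rownames(scoring$matrix)
  q <- encode_sequence(query, alphabet, "query")
  s <- encode_sequence(subject, alphabet, "subject")
  res <- .sw_align(q, s, scoring$matrix, scoring$gap_open, scoring$gap_extend)
  hit_row(res, query_id, subject_id, m = length(q), n = length(s),
          db_n = if (is.null(db_residues)) length(s) else db_residues,
          scoring = scoring)
}

hit_row <- function(res, query_id, subject_id, m, n, db_n, scoring) {
  ka <- karlin_altschul(res[["score"]], m, db_n, scoring)
  aligned_q <- if (is.na(res[["q_start"]])) 0L else res[["q_end"]] - res[["q_start"]] + 1L
  data.frame(
    query_id = query_id, subject_id = subject_id,
    raw_score = res[["score"]],
    bit_score = ka$bit_score, evalue = ka$evalue,
    identity_pct = if (res[["n_cols"]] > 0) 100 * res[["n_ident"]] / res[["n_cols"]] else 0,
    query_coverage_pct = 100 * aligned_q / m,
    q_start = res[["q_start"]], q_end = res[["q_end"]],
    s_start = res[["s_start"]], s_end = res[["s_end"]],
    stringsAsFactors = FALSE
  )
}

#' All-vs-all directed local alignment of a proteome set
#'
#' Computes one optimal local alignment per unordered protein pair (the raw
#' score is symmetric for a symmetric matrix) and reports both directed
#' hits, whose query coverages and E-values differ with the sequence
#' lengths. Self-comparisons are excluded. Output rows are sorted by
#' (query_id, subject_id).
#'
#' @param proteins A data.frame of protein records with at least
#'   `protein_id` and `sequence` columns (see [read_protein_fasta()]).
#' @param scoring A [scoring_scheme()].
#' @param db_wide_evalue If `TRUE`, E-values use the total residue count of
#'   all proteins as the search-space width (closer to a BLAST database
#'   search); default is the pairwise `m * n` space.
#' @param min_raw_score Permissive pre-filter: unordered pairs whose optimal
#'   raw score falls below this floor are omitted from the output. The
#'   default 0 keeps every pair; raise it only below any score that could
#'   pass downstream edge thresholds.
#' @return A data.frame of directed similarity hits (see [local_align()]).
#' @export
all_vs_all <- function(proteins, scoring = scoring_scheme(),
                       db_wide_evalue = FALSE, min_raw_score = 0L) {
  stopifnot(is.data.frame(proteins),
            all(c("protein_id", "sequence") %in% names(proteins)))
  if (nrow(proteins) < 2) stop("need at least 2 proteins")
  if (anyDuplicated(proteins$protein_id))
    stop("duplicate protein ids: ",
         paste(unique(proteins$protein_id[duplicated(proteins$protein_id)]),
               collapse = ", "))
  alphabet <- rownames(scoring$matrix)
  ids <- proteins$protein_id
  enc <- lapply(seq_len(nrow(proteins)), function(i)
    encode_sequence(proteins$sequence[i], alphabet, ids[i]))
  lens <- lengths(enc)
  total <- sum(lens)
  np <- length(ids)

  # pairwise results accumulated as flat vectors (one row per unordered
  # pair), expanded to both directed hits afterwards
  npairs <- np * (np - 1L) / 2L
  pi <- pj <- integer(npairs)
  stats_mat <- matrix(0L, nrow = npairs, ncol = 7L)
  k <- 0L
  for (i in seq_len(np - 1L)) {
    for (j in seq.int(i + 1L, np)) {
      res <- .sw_align(enc[[i]], enc[[j]], scoring$matrix,
                       scoring$gap_open, scoring$gap_extend)
      if (res[["score"]] < min_raw_score) next
      k <- k + 1L
      pi[k] <- i
      pj[k] <- j
      stats_mat[k, ] <- res
    }
  }
  if (k == 0L) {
    hits <- local_align("A", "A")[0, ]
    return(hits)
  }
  pi <- pi[seq_len(k)]
  pj <- pj[seq_len(k)]
  stats_mat <- stats_mat[seq_len(k), , drop = FALSE]
  score <- stats_mat[, 1]
  qs <- stats_mat[, 2]; qe <- stats_mat[, 3]
  ss <- stats_mat[, 4]; se <- stats_mat[, 5]
  n_ident <- stats_mat[, 6]; n_cols <- stats_mat[, 7]
  identity <- ifelse(n_cols > 0, 100 * n_ident / n_cols, 0)

  directed <- function(q_idx, s_idx, a_qs, a_qe, a_ss, a_se) {
    m <- lens[q_idx]
    db_n <- if (db_wide_evalue) total else lens[s_idx]
    bit <- (scoring$lambda * score - log(scoring$K)) / log(2)
    data.frame(
      query_id = ids[q_idx], subject_id = ids[s_idx],
      raw_score = score, bit_score = bit, evalue = m * db_n * 2^(-bit),
      identity_pct = identity,
      query_coverage_pct = 100 * ifelse(is.na(a_qs), 0, a_qe - a_qs + 1) / m,
      q_start = a_qs, q_end = a_qe, s_start = a_ss, s_end = a_se,
      stringsAsFactors = FALSE)
  }
  hits <- rbind(directed(pi, pj, qs, qe, ss, se),
                directed(pj, pi, ss, se, qs, qe))
  hits <- hits[order(hits$query_id, hits$subject_id), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Write directed hits as a BLAST outfmt-6-like table
#'
#' Columns: qseqid sseqid pident length evalue bitscore qstart qend sstart
#' send qcovs, tab-separated with a header line.
#'
#' @param hits Directed hit table from [all_vs_all()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  out <- data.frame(
    qseqid = hits$query_id, sseqid = hits$subject_id,
    pident = sprintf("%.2f", hits$identity_pct),
    length = ifelse(is.na(hits$q_start), 0L, hits$q_end - hits$q_start + 1L),
    evalue = format(hits$evalue, digits = 3),
    bitscore = sprintf("%.1f", hits$bit_score),
    qstart = hits$q_start, qend = hits$q_end,
    sstart = hits$s_start, send = hits$s_end,
    qcovs = sprintf("%.1f", hits$query_coverage_pct)
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
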