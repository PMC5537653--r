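#' Transfer functions to hypothetical proteins through network clusters
#'
#' For every hypothetical protein in a component containing at least one
#' non-hypothetical member, suggests the most frequent non-hypothetical
#' product in that component (ties broken lexicographically by product
#' string). Proteins in all-hypothetical components receive no suggestion;
#' existing non-hypothetical annotations are never overwritten.
#'
#' @param partition Component table from [connected_components()].
#' @param proteins Protein record data.frame (`protein_id`, `product`,
#'   `is_hypothetical`).
#' @return A data.frame of suggestions: `protein_id`, `suggested_product`,
#'   `source_cluster`, `n_support` (annotated cluster members carrying the
#'   suggested product).
#' @export
transfer_functions <- function(partition, proteins) {
  if (!all(proteins$protein_id %in% partition$protein_id))
    stop("partition does not cover all proteins")
  df <- merge(partition, proteins[, c("protein_id", "product",
                                      "is_hypothetical")],
              by = "protein_id")
  out <- list()
  for (comp in unique(df$component_id)) {
    members <- df[df$component_id == comp, , drop = FALSE]
    annotated <- members[!members$is_hypothetical, , drop = FALSE]
    hyp <- members[members$is_hypothetical, , drop = FALSE]
    if (nrow(annotated) == 0 || nrow(hyp) == 0) next
    counts <- table(annotated$product)
    top <- counts[counts == max(counts)]
    suggested <- sort(names(top))[1]
    out[[length(out) + 1L]] <- data.frame(
      protein_id = hyp$protein_id,
      suggested_product = suggested,
      source_cluster = comp,
      n_support = as.integer(counts[[suggested]]),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(protein_id = character(),
                      suggested_product = character(),
                      source_cluster = character(), n_support = integer(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$protein_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Adjusted Rand index between two labelings
#'
#' Standard pair-counting chance-corrected agreement. When the correction
#' denominator is zero (both labelings degenerate: all items together or
#' all apart), the index is defined as 0.
#'
#' @param a,b Cluster labels over the same items (equal-length vectors).
#' @return The adjusted Rand index in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (length(a) < 2) return(0)
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n2 <- choose2(length(a))
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  denom <- max_index - expected
  if (denom == 0) return(0)
  (sum_ij - expected) / denom
}

#' Congruence of two marker-gene clusterings across phages
#'
#' Each partition covers one marker's proteins (at most one marker protein
#' per phage). Phages carrying both markers are mapped to their cluster in
#' each partition and agreement is quantified by the adjusted Rand index.
#' Fewer than 3 shared phages yields `NA` (flagged as not evaluable).
#'
#' @param partition_a,partition_b Component tables (as from
#'   [connected_components()]) over the two markers' proteins.
#' @param protein_to_phage data.frame `protein_id`, `phage_id` mapping
#'   marker proteins to their phage.
#' @param marker_a,marker_b Marker names carried into the report.
#' @return A list: `marker_a`, `marker_b`, `n_shared_phages`,
#'   `adjusted_rand` (`NA` when not evaluable).
#' @export
marker_congruence <- function(partition_a, partition_b, protein_to_phage,
                              marker_a = "marker_a", marker_b = "marker_b") {
  phage_clusters <- function(partition, label) {
    df <- merge(partition, protein_to_phage, by = "protein_id")
    if (anyDuplicated(df$phage_id))
      stop(sprintf("phage %s has more than one %s protein",
                   df$phage_id[duplicated(df$phage_id)][1], label))
    stats::setNames(df$component_id, df$phage_id)
  }
  ca <- phage_clusters(partition_a, marker_a)
  cb <- phage_clusters(partition_b, marker_b)
  shared <- intersect(names(ca), names(cb))
  list(marker_a = marker_a, marker_b = marker_b,
       n_shared_phages = length(shared),
       adjusted_rand = if (length(shared) < 3) NA_real_ else
         adjusted_rand_index(ca[shared], cb[shared]))
}

#' Scan proteins for the amino-MTase catalytic motif NPP\[YFW\]
#'
#' Reports every non-overlapping occurrence of the motif IV tetrapeptide
#' NPP(Y/W/F) characteristic of N6-adenine (and N4-cytosine) DNA
#' methyltransferases, left to right.
#'
#' @param proteins Protein record data.frame (`protein_id`, `sequence`);
#'   a single record (one-row data.frame) works too.
#' @return A data.frame of calls: `protein_id`, `motif` (matched string),
#'   `motif_position` (1-based residue index). Zero rows when nothing
#'   matches.
#' @export
scan_mtase_motif <- function(proteins) {
  out <- list()
  for (i in seq_len(nrow(proteins))) {
    m <- gregexpr("NPP[YFW]", proteins$sequence[i])[[1]]
    if (m[1] == -1) next
    out[[length(out) + 1L]] <- data.frame(
      protein_id = proteins$protein_id[i],
      motif = regmatches(proteins$sequence[i], list(m))[[1]],
      motif_position = as.integer(m),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(protein_id = character(), motif = character(),
                      motif_position = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Gene-order distance of MTase calls to the nearest replication gene
#'
#' Orders the CDS features along the replicon and annotates each motif
#' call with the minimal absolute difference in CDS ordinal position to
#' the nearest replication-labeled gene (`NA` when the prophage carries no
#' replication gene or the protein has no CDS feature).
#'
#' @param calls MTase call table from [scan_mtase_motif()].
#' @param features Feature data.frame including the CDS rows (with
#'   `protein_id` and `product`).
#' @param replication_keywords Patterns (regex, case-insensitive) that
#'   identify replication-module genes by product.
#' @return `calls` with an added `gene_distance_to_replication` column.
#' @export
replication_proximity <- function(calls, features,
                                  replication_keywords = "replication") {
  cds <- features[features$kind == "CDS", , drop = FALSE]
  cds <- cds[order(cds$replicon_id, cds$start), , drop = FALSE]
  cds$ordinal <- stats::ave(cds$start, cds$replicon_id,
                            FUN = seq_along)
  is_repl <- Reduce(`|`, lapply(replication_keywords, function(kw)
    grepl(kw, cds$product, ignore.case = TRUE)))
  is_repl[is.na(is_repl)] <- FALSE
  calls$gene_distance_to_replication <- NA_integer_
  for (i in seq_len(nrow(calls))) {
    row <- cds[!is.na(cds$protein_id) &
                 cds$protein_id == calls$protein_id[i], , drop = FALSE]
    if (nrow(row) == 0) next
    repl <- cds[is_repl & cds$replicon_id == row$replicon_id[1], ,
                drop = FALSE]
    if (nrow(repl) == 0) next
    calls$gene_distance_to_replication[i] <-
      min(abs(repl$ordinal - row$ordinal[1]))
  }
  calls
}
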