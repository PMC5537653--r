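log_stage <- function(fmt, ...) {
  message(sprintf(paste0("[viromenet] ", fmt), ...))
}

#' Simulate a full synthetic study dataset to disk
#'
#' Drives [generate_dataset()] and [generate_host_with_prophage()] and
#' writes `proteins.fasta`, `truth.tsv`, `host.fasta`, `features.gff3` and
#' `att_truth.tsv` under `out_dir`. Identical configurations (same seed)
#' produce byte-identical files.
#'
#' @param config A [synth_config()]; its seed governs all randomness,
#'   including the host/prophage generation.
#' @param out_dir Output directory (created if missing).
#' @param prophages List of [prophage_spec()] objects to plant, one host
#'   replicon each; `NULL` skips host generation.
#' @param host_gc Host background GC percent.
#' @return Named character vector of written paths, invisibly.
#' @export
run_simulate <- function(config, out_dir, prophages = NULL, host_gc = 62) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dataset <- generate_dataset(config)
  paths <- c(proteins = file.path(out_dir, "proteins.fasta"),
             truth = file.path(out_dir, "truth.tsv"))
  write_protein_fasta(dataset$proteins, paths[["proteins"]])
  utils::write.table(dataset$truth, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  log_stage("simulate: %d proteins (%d families, %d singletons)",
            nrow(dataset$proteins), length(config$families),
            config$n_singletons)
  if (!is.null(prophages)) {
    seqs <- character(0)
    feats <- list()
    truths <- list()
    for (k in seq_along(prophages)) {
      host <- generate_host_with_prophage(
        prophages[[k]], host_gc = host_gc,
        replicon_id = sprintf("replicon_%d", k),
        phage_name = sprintf("phiSyn%d", k))
      seqs[sprintf("replicon_%d", k)] <- host$sequence
      feats[[k]] <- host$features
      tr <- host$att_truth
      tr$replicon_id <- sprintf("replicon_%d", k)
      truths[[k]] <- tr
    }
    paths <- c(paths, host = file.path(out_dir, "host.fasta"),
               features = file.path(out_dir, "features.gff3"),
               att_truth = file.path(out_dir, "att_truth.tsv"))
    set <- Biostrings::DNAStringSet(seqs)
    Biostrings::writeXStringSet(set, paths[["host"]], width = 70L)
    write_feature_table(do.call(rbind, feats), paths[["features"]])
    utils::write.table(do.call(rbind, truths), paths[["att_truth"]],
                       sep = "\t", quote = FALSE, row.names = FALSE, na = "")
    log_stage("simulate: %d host replicon(s) with planted prophages",
              length(prophages))
  }
  invisible(paths)
}

#' Run the all-vs-all network stage on a protein FASTA
#'
#' Chains [all_vs_all()], [build_network()], [connected_components()] and
#' [summarize_components()], writing `hits.tsv`, `edges.tsv`,
#' `network.graphml`, `components.tsv` and `summary.json` under `out_dir`.
#'
#' @param proteins_fasta Protein FASTA (see [read_protein_fasta()]).
#' @param out_dir Output directory (created if missing).
#' @param thresholds An [edge_thresholds()].
#' @param scoring A [scoring_scheme()].
#' @return The `cluster_summary`, invisibly.
#' @export
run_network <- function(proteins_fasta, out_dir,
                        thresholds = edge_thresholds(),
                        scoring = scoring_scheme()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  proteins <- read_protein_fasta(proteins_fasta)
  if (nrow(proteins) < 2) stop("need at least 2 proteins")
  t0 <- proc.time()[["elapsed"]]
  hits <- all_vs_all(proteins, scoring)
  log_stage("network: %d directed hits from %d proteins (%.1f s)",
            nrow(hits), nrow(proteins), proc.time()[["elapsed"]] - t0)
  net <- build_network(hits, proteins, thresholds)
  partition <- connected_components(net)
  summary <- summarize_components(partition, net)
  write_hits(hits, file.path(out_dir, "hits.tsv"))
  write_network(net, file.path(out_dir, "edges.tsv"), "edge_list")
  write_network(net, file.path(out_dir, "network.graphml"), "graphml")
  utils::write.table(partition, file.path(out_dir, "components.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  json <- list(
    thresholds = list(evalue_max = thresholds$evalue_max,
                      identity_min = thresholds$identity_min,
                      coverage_min = thresholds$coverage_min),
    n_nodes = summary$n_nodes, n_edges = summary$n_edges,
    n_multi_subgraphs = summary$n_multi_subgraphs,
    n_singletons = summary$n_singletons,
    n_clustered_nodes = summary$n_clustered_nodes,
    pct_clustered = summary$pct_clustered,
    size_distribution = summary$distribution_string)
  jsonlite::write_json(json, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_stage("network: %d edges, %d subgraphs, %d singletons, %.1f%% clustered",
            summary$n_edges, summary$n_multi_subgraphs,
            summary$n_singletons, summary$pct_clustered)
  invisible(summary)
}

#' Run the annotation stage
#'
#' Function transfer over network components plus MTase motif scanning
#' (with replication proximity when features are given). Writes
#' `suggestions.tsv` and `mtase_calls.tsv` under `out_dir`.
#'
#' @param proteins_fasta Protein FASTA.
#' @param components_tsv Component table written by [run_network()].
#' @param out_dir Output directory.
#' @param features_gff3 Optional GFF3 with CDS features for replication
#'   proximity.
#' @return A list with `suggestions` and `mtase_calls`, invisibly.
#' @export
run_annotate <- function(proteins_fasta, components_tsv, out_dir,
                         features_gff3 = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  proteins <- read_protein_fasta(proteins_fasta)
  partition <- utils::read.delim(components_tsv, stringsAsFactors = FALSE)
  suggestions <- transfer_functions(partition, proteins)
  calls <- scan_mtase_motif(proteins)
  if (!is.null(features_gff3)) {
    features <- read_feature_table(features_gff3)
    calls <- replication_proximity(calls, features)
  }
  utils::write.table(suggestions, file.path(out_dir, "suggestions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(calls, file.path(out_dir, "mtase_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  log_stage("annotate: %d suggestions, %d motif calls",
            nrow(suggestions), nrow(calls))
  invisible(list(suggestions = suggestions, mtase_calls = calls))
}

#' Run attachment-site detection over annotated prophage regions
#'
#' For every `prophage_region` feature, scans for the attL/attR direct
#' repeat and checks tRNA reconstitution. Writes a BED-like `att.tsv`
#' (1-based inclusive coordinates) under `out_dir`.
#'
#' @param host_fasta Nucleotide FASTA of host replicons.
#' @param features_gff3 GFF3 with `prophage_region` and `tRNA` features.
#' @param out_dir Output directory.
#' @param max_prefix,window,min_len Detector parameters, see
#'   [find_att_repeat()].
#' @return The att table, invisibly.
#' @export
run_att <- function(host_fasta, features_gff3, out_dir,
                    max_prefix = 200L, window = 1000L, min_len = 10L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- Biostrings::readDNAStringSet(host_fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  features <- read_feature_table(features_gff3)
  regions <- features[features$kind == "prophage_region", , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(regions))) {
    reg <- regions[i, ]
    replicon <- as.character(seqs[[reg$replicon_id]])
    att <- find_att_repeat(replicon, reg$start, reg$end,
                           max_prefix = max_prefix, window = window,
                           min_len = min_len)
    if (is.null(att)) {
      rows[[length(rows) + 1L]] <- data.frame(
        replicon_id = reg$replicon_id, region_name = reg$name,
        repeat_length = 0L, attL_start = NA_integer_,
        attL_end = NA_integer_, attR_start = NA_integer_,
        attR_end = NA_integer_, anchor_trna = NA_character_,
        reconstituted = FALSE, stringsAsFactors = FALSE)
      next
    }
    chk <- check_trna_reconstitution(
      att, features[features$replicon_id == reg$replicon_id, , drop = FALSE])
    rows[[length(rows) + 1L]] <- data.frame(
      replicon_id = reg$replicon_id, region_name = reg$name,
      repeat_length = chk$att$repeat_length,
      attL_start = chk$att$attL_start, attL_end = chk$att$attL_end,
      attR_start = chk$att$attR_start, attR_end = chk$att$attR_end,
      anchor_trna = chk$att$anchor_trna,
      reconstituted = chk$reconstituted, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  utils::write.table(out, file.path(out_dir, "att.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  log_stage("att: %d region(s), %d with detected repeats",
            nrow(out), sum(out$repeat_length > 0))
  invisible(out)
}

#' Run per-prophage genome statistics
#'
#' Builds the comparative summary table (coordinates, size, gene count,
#' coding density, GC, integration site) for every `prophage_region`
#' feature and writes `prophage_summary.tsv` under `out_dir`.
#'
#' @param host_fasta Nucleotide FASTA of host replicons.
#' @param features_gff3 GFF3 with features.
#' @param out_dir Output directory.
#' @return The summary table, invisibly.
#' @export
run_stats <- function(host_fasta, features_gff3, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- Biostrings::readDNAStringSet(host_fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  features <- read_feature_table(features_gff3)
  regions <- features[features$kind == "prophage_region", , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(regions))) {
    reg <- regions[i, ]
    replicon <- as.character(seqs[[reg$replicon_id]])
    repl_feats <- features[features$replicon_id == reg$replicon_id, ,
                           drop = FALSE]
    trna <- repl_feats[repl_feats$kind == "tRNA" &
                         repl_feats$end >= reg$start - 200L &
                         repl_feats$start <= reg$end, , drop = FALSE]
    row <- prophage_summary_row(
      name = reg$name, host = reg$replicon_id, accession = reg$replicon_id,
      region_start = reg$start, region_end = reg$end,
      sequence = replicon, features = repl_feats,
      integration_site = if (nrow(trna) > 0) trna$trna_isotype[1]
      else NA_character_)
    cs <- coding_stats(repl_feats, reg$start, reg$end)
    row$coding_density_pct <- round_half_up(cs$coding_density_pct, 1)
    rows[[length(rows) + 1L]] <- row
  }
  out <- do.call(rbind, rows)
  utils::write.table(out, file.path(out_dir, "prophage_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  log_stage("stats: %d prophage region(s) summarized", nrow(out))
  invisible(out)
}
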