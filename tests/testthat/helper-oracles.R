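# Independent oracles used to cross-check the implementation. These are
# deliberately simple, separately coded routines: a score-only pure-R
# affine-gap Smith-Waterman, a recursive-DFS connected-components finder,
# and a per-base bitmap for coding density.

blosum62_matrix <- local({
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  env$BLOSUM62
})

# Score-only affine-gap local alignment; gap of length L costs open + L*ext.
sw_score_oracle <- function(q, s, mat = blosum62_matrix, open = 11, ext = 1) {
  qc <- strsplit(q, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  m <- length(qc); n <- length(sc); NEG <- -1e9
  M <- matrix(0, m + 1, n + 1)
  X <- matrix(NEG, m + 1, n + 1)
  Y <- matrix(NEG, m + 1, n + 1)
  best <- 0
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      sub <- mat[qc[i - 1], sc[j - 1]]
      M[i, j] <- sub + max(0, M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext)
      Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext)
      best <- max(best, M[i, j])
    }
  }
  best
}

# Connected components by iterative depth-first search over an adjacency
# list; components labeled by their smallest member id.
dfs_components_oracle <- function(node_ids, edge_a, edge_b) {
  adj <- stats::setNames(vector("list", length(node_ids)), node_ids)
  for (k in seq_along(edge_a)) {
    adj[[edge_a[k]]] <- c(adj[[edge_a[k]]], edge_b[k])
    adj[[edge_b[k]]] <- c(adj[[edge_b[k]]], edge_a[k])
  }
  seen <- stats::setNames(rep(FALSE, length(node_ids)), node_ids)
  comp <- stats::setNames(rep(NA_character_, length(node_ids)), node_ids)
  for (root in node_ids) {
    if (seen[[root]]) next
    stack <- root
    members <- character(0)
    while (length(stack) > 0) {
      v <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      if (seen[[v]]) next
      seen[[v]] <- TRUE
      members <- c(members, v)
      stack <- c(stack, adj[[v]])
    }
    comp[members] <- min(members)
  }
  comp
}

# Per-base bitmap coding coverage of a region.
coding_bitmap_oracle <- function(starts, ends, region_start, region_end) {
  covered <- rep(FALSE, region_end - region_start + 1)
  for (k in seq_along(starts)) {
    a <- max(starts[k], region_start)
    b <- min(ends[k], region_end)
    if (a <= b) covered[(a - region_start + 1):(b - region_start + 1)] <- TRUE
  }
  sum(covered)
}

random_aa_string <- function(n, alphabet = c("A", "C", "D", "W")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

AA_FULL <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
             "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Small labeled proteome with planted families used by several tests.
make_test_dataset <- function(seed = 11) {
  cfg <- synth_config(seed,
    families = list(
      family_spec("FA", paste0("P", 1:5), 220, 90, "holin"),
      family_spec("FB", paste0("P", 1:4), 260, 90,
                  "terminase large subunit")),
    n_singletons = 3)
  generate_dataset(cfg)
}
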