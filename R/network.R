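#' Edge thresholds for the reciprocated similarity network
#'
#' Defaults follow the standard all-vs-all BLASTP filtering used for
#' (pro)phage protein networks: E-value at most 1e-5, at least 50 percent
#' identity and at least 50 percent query coverage, required of *both*
#' directed hits. Boundary values pass (comparisons use <= / >=).
#'
#' @param evalue_max Maximum E-value.
#' @param identity_min Minimum percent identity in \[0, 100\].
#' @param coverage_min Minimum percent query coverage in \[0, 100\].
#' @return An `edge_thresholds` list.
#' @export
edge_thresholds <- function(evalue_max = 1e-5, identity_min = 50,
                            coverage_min = 50) {
  stopifnot(is.finite(evalue_max), is.finite(identity_min),
            is.finite(coverage_min),
            identity_min >= 0, identity_min <= 100,
            coverage_min >= 0, coverage_min <= 100)
  structure(list(evalue_max = evalue_max, identity_min = identity_min,
                 coverage_min = coverage_min), class = "edge_thresholds")
}

hit_passes <- function(hits, thresholds) {
  hits$evalue <= thresholds$evalue_max &
    hits$identity_pct >= thresholds$identity_min &
    hits$query_coverage_pct >= thresholds$coverage_min
}

#' Build the reciprocated protein similarity network
#'
#' An undirected edge (a, b) exists iff the directed hit a->b AND the
#' directed hit b->a each satisfy all three thresholds. The node universe
#' is supplied explicitly so proteins without any passing hit remain in
#' the graph as isolated nodes (one-element clusters).
#'
#' @param hits Directed hit table from [all_vs_all()].
#' @param proteins Node universe: protein record data.frame (`protein_id`,
#'   `phage_id`, `product`).
#' @param thresholds An [edge_thresholds()].
#' @return A `protein_network`: list with `graph` (igraph, node attributes
#'   `phage_id`, `product`, `degree`), `nodes`, `edges` (data.frame
#'   `protein_a`, `protein_b`, `identity` = min of the two directed
#'   identities, `coverage` = min of the two directed coverages, `evalue`
#'   = max of the two directed E-values) and `thresholds`.
#' @export
build_network <- function(hits, proteins, thresholds = edge_thresholds()) {
  stopifnot(inherits(thresholds, "edge_thresholds"))
  ids <- proteins$protein_id
  unknown <- setdiff(unique(c(hits$query_id, hits$subject_id)), ids)
  if (length(unknown) > 0)
    stop("hit references unknown protein: ", unknown[1])

  edges <- data.frame(protein_a = character(), protein_b = character(),
                      identity = numeric(), coverage = numeric(),
                      evalue = numeric(), stringsAsFactors = FALSE)
  if (nrow(hits) > 0) {
    pass <- hits[hit_passes(hits, thresholds), , drop = FALSE]
    if (nrow(pass) > 0) {
      a <- pmin(pass$query_id, pass$subject_id)
      b <- pmax(pass$query_id, pass$subject_id)
      key <- paste(a, b, sep = "\r")
      tab <- table(key)
      reciprocated <- names(tab)[tab == 2L]
      if (length(reciprocated) > 0) {
        sel <- pass[key %in% reciprocated, , drop = FALSE]
        ka <- pmin(sel$query_id, sel$subject_id)
        kb <- pmax(sel$query_id, sel$subject_id)
        kk <- paste(ka, kb, sep = "\r")
        ord_keys <- sort(unique(kk))
        parts <- do.call(rbind, strsplit(ord_keys, "\r", fixed = TRUE))
        edges <- data.frame(
          protein_a = parts[, 1], protein_b = parts[, 2],
          identity = as.numeric(tapply(sel$identity_pct, kk, min)[ord_keys]),
          coverage = as.numeric(tapply(sel$query_coverage_pct, kk, min)[ord_keys]),
          evalue = as.numeric(tapply(sel$evalue, kk, max)[ord_keys]),
          stringsAsFactors = FALSE)
      }
    }
  }

  vertices <- data.frame(name = ids,
                         phage_id = proteins$phage_id %||% NA_character_,
                         product = proteins$product %||% NA_character_,
                         stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = vertices)
  igraph::V(g)$degree <- igraph::degree(g)
  structure(list(graph = g, nodes = proteins, edges = edges,
                 thresholds = thresholds),
            class = "protein_network")
}

#' @export
print.protein_network <- function(x, ...) {
  cat(sprintf("<protein_network> %d nodes, %d edges (E<=%g, id>=%g%%, cov>=%g%%)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              x$thresholds$evalue_max, x$thresholds$identity_min,
              x$thresholds$coverage_min))
  invisible(x)
}

#' Connected components of the similarity network
#'
#' Components are the network's protein groups ("subgraphs"). Component
#' ids are assigned deterministically as the lexicographically smallest
#' member protein id.
#'
#' @param net A `protein_network` from [build_network()].
#' @return A data.frame `protein_id`, `component_id`, `size` (component
#'   size), one row per node.
#' @export
connected_components <- function(net) {
  comp <- igraph::components(net$graph)
  ids <- igraph::V(net$graph)$name
  member <- comp$membership
  comp_id <- stats::ave(ids, member, FUN = min)
  sizes <- as.integer(stats::ave(ids, member, FUN = length))
  out <- data.frame(protein_id = ids, component_id = comp_id, size = sizes,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Summarize a network partition
#'
#' Computes the cluster summary statistics: node/edge counts, the
#' subgraph-size distribution over multi-node components, the number of
#' multi-node subgraphs and singleton (one-element) clusters, the number
#' and percentage of clustered nodes. The percentage is rounded half-up to
#' one decimal.
#'
#' @param partition Component table from [connected_components()].
#' @param net The `protein_network` (for the edge count); may be `NULL`.
#' @return A `cluster_summary` list: `n_nodes`, `n_edges`,
#'   `size_distribution` (data.frame `size`, `count`, size descending),
#'   `distribution_string` (rendered `"<s>s:<n>n"` comma-joined),
#'   `n_multi_subgraphs`, `n_singletons`, `n_clustered_nodes`,
#'   `pct_clustered`.
#' @export
summarize_components <- function(partition, net = NULL) {
  sizes <- table(partition$component_id)
  multi <- sizes[sizes >= 2]
  dist <- if (length(multi) > 0) {
    d <- as.data.frame(table(size = as.integer(multi)),
                       stringsAsFactors = FALSE)
    d$size <- as.integer(as.character(d$size))
    names(d)[2] <- "count"
    d <- d[order(-d$size), , drop = FALSE]
    rownames(d) <- NULL
    d
  } else data.frame(size = integer(), count = integer())
  n_nodes <- nrow(partition)
  n_clustered <- sum(as.integer(multi))
  n_singletons <- sum(sizes == 1)
  structure(list(
    n_nodes = n_nodes,
    n_edges = if (is.null(net)) NA_integer_ else igraph::ecount(net$graph),
    size_distribution = dist,
    distribution_string = render_size_distribution(dist),
    n_multi_subgraphs = length(multi),
    n_singletons = n_singletons,
    n_clustered_nodes = n_clustered,
    pct_clustered = if (n_nodes > 0)
      round_half_up(100 * n_clustered / n_nodes, 1) else NA_real_
  ), class = "cluster_summary")
}

#' @export
print.cluster_summary <- function(x, ...) {
  cat(sprintf(
    "<cluster_summary> %d nodes, %s edges; %d subgraphs + %d singletons; %d (%s%%) clustered\n",
    x$n_nodes, format(x$n_edges), x$n_multi_subgraphs, x$n_singletons,
    x$n_clustered_nodes, format(x$pct_clustered, nsmall = 1)))
  if (nrow(x$size_distribution) > 0)
    cat(" ", x$distribution_string, "\n")
  invisible(x)
}

#' Render a subgraph-size distribution as `"<s>s:<n>n"` tokens
#'
#' @param dist data.frame with `size` and `count` columns.
#' @return A single string, tokens comma-joined with size descending;
#'   empty string for an empty distribution.
#' @export
render_size_distribution <- function(dist) {
  if (nrow(dist) == 0) return("")
  dist <- dist[order(-dist$size), , drop = FALSE]
  paste(sprintf("%ds:%dn", dist$size, dist$count), collapse = ", ")
}

#' Parse a subgraph-size distribution string
#'
#' Inverse of [render_size_distribution()]: parses comma-separated tokens
#' of the form `"<size>s:<count>n"` (e.g. `"12s:6n, 2s:175n"`).
#'
#' @param text Distribution string; `""` yields an empty distribution.
#' @return data.frame with `size` and `count`, in token order.
#' @export
parse_size_distribution <- function(text) {
  text <- trimws(text)
  if (!nzchar(text)) return(data.frame(size = integer(), count = integer()))
  tokens <- trimws(strsplit(text, ",", fixed = TRUE)[[1]])
  m <- regmatches(tokens, regexec("^([0-9]+)s:([0-9]+)n$", tokens))
  bad <- lengths(m) != 3L
  if (any(bad)) stop("malformed distribution token: '", tokens[bad][1], "'")
  data.frame(size = as.integer(vapply(m, `[`, "", 2L)),
             count = as.integer(vapply(m, `[`, "", 3L)))
}
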