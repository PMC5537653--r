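mkhit <- function(q, s, identity = 90, coverage = 95, evalue = 1e-30) {
  data.frame(query_id = q, subject_id = s, raw_score = 500, bit_score = 100,
             evalue = evalue, identity_pct = identity,
             query_coverage_pct = coverage, q_start = 1L, q_end = 10L,
             s_start = 1L, s_end = 10L, stringsAsFactors = FALSE)
}

mknodes <- function(ids) {
  data.frame(protein_id = ids, phage_id = "P1", product = "x",
             sequence = "M", stringsAsFactors = FALSE)
}

test_that("edges require reciprocation: both directed hits must pass", {
  nodes <- mknodes(c("a", "b"))
  hits <- rbind(mkhit("a", "b"), mkhit("b", "a", coverage = 30))
  net <- build_network(hits, nodes)
  expect_equal(igraph::ecount(net$graph), 0)

  both <- rbind(mkhit("a", "b"), mkhit("b", "a"))
  net2 <- build_network(both, nodes)
  expect_equal(igraph::ecount(net2$graph), 1)

  # boundary values pass (<= / >=)
  edge <- rbind(mkhit("a", "b", identity = 50, coverage = 50, evalue = 1e-5),
                mkhit("b", "a", identity = 50, coverage = 50, evalue = 1e-5))
  expect_equal(igraph::ecount(build_network(edge, nodes)$graph), 1)

  expect_error(build_network(mkhit("a", "zz"), nodes), "unknown protein: zz")
})

test_that("edge statistics combine the two directions conservatively", {
  nodes <- mknodes(c("a", "b"))
  hits <- rbind(mkhit("a", "b", identity = 80, coverage = 90, evalue = 1e-30),
                mkhit("b", "a", identity = 75, coverage = 60, evalue = 1e-20))
  net <- build_network(hits, nodes)
  expect_equal(net$edges$identity, 75)
  expect_equal(net$edges$coverage, 60)
  expect_equal(net$edges$evalue, 1e-20)
})

test_that("five identical proteins give the complete graph K5", {
  proteins <- data.frame(
    protein_id = paste0("p", 1:5), phage_id = "P1", product = "holin",
    sequence = strrep("MKTAYIAKQRWGHEE", 10), stringsAsFactors = FALSE)
  net <- build_network(all_vs_all(proteins), proteins)
  expect_equal(igraph::ecount(net$graph), 10)
  expect_true(all(igraph::V(net$graph)$degree == 4))
})

test_that("network edge set equals a double-loop filter oracle", {
  d <- make_test_dataset(41)
  hits <- all_vs_all(d$proteins)
  th <- edge_thresholds()
  net <- build_network(hits, d$proteins, th)
  got <- sort(paste(net$edges$protein_a, net$edges$protein_b))

  # independently coded double loop over the directed hit table
  expected <- character(0)
  ids <- d$proteins$protein_id
  for (a in ids) for (b in ids) {
    if (a >= b) next
    fwd <- hits[hits$query_id == a & hits$subject_id == b, ]
    rev <- hits[hits$query_id == b & hits$subject_id == a, ]
    ok <- function(h) nrow(h) == 1 && h$evalue <= th$evalue_max &&
      h$identity_pct >= th$identity_min &&
      h$query_coverage_pct >= th$coverage_min
    if (ok(fwd) && ok(rev)) expected <- c(expected, paste(a, b))
  }
  expect_setequal(got, expected)
})

test_that("relaxing thresholds never removes edges and never lowers clustering", {
  d <- make_test_dataset(42)
  hits <- all_vs_all(d$proteins)
  sweeps <- list(edge_thresholds(identity_min = 90, coverage_min = 90),
                 edge_thresholds(identity_min = 70, coverage_min = 70),
                 edge_thresholds(identity_min = 50, coverage_min = 50),
                 edge_thresholds(evalue_max = 1e-2, identity_min = 30,
                                 coverage_min = 30))
  prev_edges <- character(0)
  prev_pct <- -1
  for (th in sweeps) {
    net <- build_network(hits, d$proteins, th)
    edges <- paste(net$edges$protein_a, net$edges$protein_b)
    expect_true(all(prev_edges %in% edges))
    s <- summarize_components(connected_components(net), net)
    expect_gte(s$pct_clustered, prev_pct)
    prev_edges <- edges
    prev_pct <- s$pct_clustered
  }
})

test_that("connected components match a DFS oracle and label deterministically", {
  nodes <- mknodes(c("a", "b", "c", "d"))
  net <- build_network(mkhit("a", "b")[0, ], nodes)
  part <- connected_components(net)
  expect_equal(nrow(part), 4)
  expect_true(all(part$size == 1))
  expect_equal(part$component_id, part$protein_id)

  path_hits <- rbind(mkhit("a", "b"), mkhit("b", "a"),
                     mkhit("b", "c"), mkhit("c", "b"))
  net2 <- build_network(path_hits, nodes)
  part2 <- connected_components(net2)
  expect_equal(part2$component_id[part2$protein_id %in% c("a", "b", "c")],
               rep("a", 3))
  expect_equal(part2$component_id[part2$protein_id == "d"], "d")

  # random graphs vs the independent DFS oracle
  withr::with_seed(43, {
    for (rep in 1:5) {
      ids <- sprintf("n%03d", 1:200)
      n_edges <- 150
      ea <- sample(ids, n_edges, replace = TRUE)
      eb <- sample(ids, n_edges, replace = TRUE)
      keep <- ea != eb
      ea <- ea[keep]; eb <- eb[keep]
      pair_key <- paste(pmin(ea, eb), pmax(ea, eb))
      dedup <- !duplicated(pair_key)
      ea <- ea[dedup]; eb <- eb[dedup]
      hits <- rbind(do.call(rbind, Map(mkhit, ea, eb)),
                    do.call(rbind, Map(mkhit, eb, ea)))
      net <- build_network(hits, mknodes(ids))
      part <- connected_components(net)
      oracle <- dfs_components_oracle(ids, ea, eb)
      expect_equal(stats::setNames(part$component_id, part$protein_id)[ids],
                   oracle)
    }
  })
})

test_that("cluster summaries satisfy their accounting identities", {
  # partition reconstructed from a known size distribution
  dist <- data.frame(size = c(5L, 3L, 2L), count = c(1L, 2L, 4L))
  comp_sizes <- rep(dist$size, dist$count)
  n_singletons <- 7L
  sizes_all <- c(comp_sizes, rep(1L, n_singletons))
  partition <- data.frame(
    protein_id = sprintf("p%03d", seq_len(sum(sizes_all))),
    component_id = rep(sprintf("c%02d", seq_along(sizes_all)), sizes_all),
    stringsAsFactors = FALSE)
  s <- summarize_components(partition)
  expect_equal(s$n_nodes, sum(sizes_all))
  expect_equal(s$n_clustered_nodes, sum(dist$size * dist$count))
  expect_equal(s$n_singletons, n_singletons)
  expect_equal(s$n_multi_subgraphs, sum(dist$count))
  expect_equal(s$size_distribution, dist)
  expect_equal(s$distribution_string, "5s:1n, 3s:2n, 2s:4n")
  expect_equal(s$n_clustered_nodes + s$n_singletons, s$n_nodes)
  expect_equal(s$pct_clustered,
               round(100 * s$n_clustered_nodes / s$n_nodes, 1))

  # degenerate cases
  all_single <- data.frame(protein_id = letters[1:4],
                           component_id = letters[1:4])
  s0 <- summarize_components(all_single)
  expect_equal(s0$pct_clustered, 0.0)
  expect_equal(nrow(s0$size_distribution), 0)
  expect_equal(s0$distribution_string, "")

  k3 <- data.frame(protein_id = letters[1:3], component_id = "a")
  expect_equal(summarize_components(k3)$pct_clustered, 100.0)
})

test_that("distribution strings parse and render as exact inverses", {
  expect_equal(parse_size_distribution("2s:175n"),
               data.frame(size = 2L, count = 175L))
  expect_equal(nrow(parse_size_distribution("")), 0)
  expect_error(parse_size_distribution("3s:4n, 5x:2n"),
               "malformed distribution token: '5x:2n'")

  withr::with_seed(44, {
    for (rep in 1:100) {
      sizes <- sort(sample(2:50, sample(1:8, 1)), decreasing = TRUE)
      dist <- data.frame(size = sizes,
                         count = sample(1:300, length(sizes), TRUE))
      expect_equal(parse_size_distribution(render_size_distribution(dist)),
                   dist)
    }
  })
})
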