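test_that("function transfer suggests the majority non-hypothetical product", {
  partition <- data.frame(
    protein_id = c("h1", "a1", "a2", "h2", "h3", "h4", "h5"),
    component_id = c("c1", "c1", "c1", "c2", "c2", "c2", "c2"),
    stringsAsFactors = FALSE)
  proteins <- data.frame(
    protein_id = partition$protein_id,
    product = c("hypothetical protein", "holin", "holin",
                rep("hypothetical protein", 4)),
    is_hypothetical = c(TRUE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  s <- transfer_functions(partition, proteins)
  expect_equal(nrow(s), 1)  # all-hypothetical c2 gets nothing
  expect_equal(s$protein_id, "h1")
  expect_equal(s$suggested_product, "holin")
  expect_equal(s$n_support, 2L)
  expect_equal(s$source_cluster, "c1")
})

test_that("majority ties break lexicographically and annotations are never overwritten", {
  partition <- data.frame(protein_id = c("h1", "a1", "a2"),
                          component_id = "c1", stringsAsFactors = FALSE)
  proteins <- data.frame(
    protein_id = c("h1", "a1", "a2"),
    product = c("hypothetical protein", "portal protein", "holin"),
    is_hypothetical = c(TRUE, FALSE, FALSE), stringsAsFactors = FALSE)
  s <- transfer_functions(partition, proteins)
  expect_equal(s$suggested_product, "holin")  # tie 1-1, lexicographic
  # annotated members receive no suggestion
  expect_false(any(s$protein_id %in% c("a1", "a2")))
})

test_that("planted hypothetical members recover their family's label", {
  withr::with_seed(51, {
    cfg <- synth_config(51, families = list(
      family_spec("FA", paste0("P", 1:6), 200, 90, "holin"),
      family_spec("FB", paste0("P", 1:5), 240, 90, "portal protein")),
      n_singletons = 5)
    d <- generate_dataset(cfg)
  })
  # demote some labeled family members to hypothetical
  planted <- c("FA_m2", "FA_m5", "FB_m1", "FB_m4")
  d$proteins$product[d$proteins$protein_id %in% planted] <-
    "hypothetical protein"
  d$proteins$is_hypothetical <-
    is_hypothetical_label(d$proteins$product)
  net <- build_network(all_vs_all(d$proteins), d$proteins)
  partition <- connected_components(net)
  s <- transfer_functions(partition, d$proteins)
  expect_setequal(s$protein_id, planted)
  expect_equal(s$suggested_product[s$protein_id == "FA_m2"], "holin")
  expect_equal(s$suggested_product[s$protein_id == "FB_m4"],
               "portal protein")
})

test_that("suggestion count is non-increasing as thresholds tighten", {
  withr::with_seed(52, {
    cfg <- synth_config(52, families = list(
      family_spec("FA", paste0("P", 1:5), 200, 70, "holin"),
      family_spec("FB", paste0("P", 1:4), 220, 60, "integrase")),
      n_singletons = 4)
    d <- generate_dataset(cfg)
  })
  demote <- c("FA_m1", "FB_m2")
  d$proteins$product[d$proteins$protein_id %in% demote] <-
    "hypothetical protein"
  d$proteins$is_hypothetical <- is_hypothetical_label(d$proteins$product)
  hits <- all_vs_all(d$proteins)
  counts <- vapply(c(50, 65, 80, 95), function(idmin) {
    net <- build_network(hits, d$proteins,
                         edge_thresholds(identity_min = idmin))
    nrow(transfer_functions(connected_components(net), d$proteins))
  }, 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("adjusted Rand index behaves at its anchors and matches mclust", {
  a <- c(1, 1, 2, 2, 3, 3)
  expect_equal(adjusted_rand_index(a, a), 1)
  expect_equal(adjusted_rand_index(rep(1, 6), 1:6), 0)
  # degenerate convention: both partitions trivial
  expect_equal(adjusted_rand_index(rep(1, 5), rep(2, 5)), 0)

  skip_if_not_installed("mclust")
  withr::with_seed(53, {
    for (rep in 1:20) {
      x <- sample(1:4, 30, TRUE)
      y <- sample(1:4, 30, TRUE)
      expect_equal(adjusted_rand_index(x, y),
                   unname(mclust::adjustedRandIndex(x, y)))
    }
  })
})

test_that("random partitions have null-centered adjusted Rand index", {
  withr::with_seed(54, {
    aris <- replicate(1000, {
      adjusted_rand_index(sample(1:4, 20, TRUE), sample(1:4, 20, TRUE))
    })
  })
  expect_lt(abs(mean(aris)), 0.05)
})

test_that("marker congruence maps phages to clusters and flags small overlap", {
  part <- function(ids, comps) data.frame(protein_id = ids,
                                          component_id = comps,
                                          stringsAsFactors = FALSE)
  map <- data.frame(protein_id = c(paste0("t", 1:6), paste0("m", 1:6)),
                    phage_id = rep(paste0("phage", 1:6), 2),
                    stringsAsFactors = FALSE)
  pa <- part(paste0("t", 1:6), c("A", "A", "B", "B", "C", "C"))
  pb <- part(paste0("m", 1:6), c("X", "X", "Y", "Y", "Z", "Z"))
  rep_ab <- marker_congruence(pa, pb, map, "TerL", "MCP")
  expect_equal(rep_ab$n_shared_phages, 6)
  expect_equal(rep_ab$adjusted_rand, 1.0)
  expect_equal(rep_ab$marker_a, "TerL")

  # fewer than 3 shared phages -> flagged NA
  small <- marker_congruence(part("t1", "A"), part("m1", "X"), map)
  expect_equal(small$n_shared_phages, 1)
  expect_true(is.na(small$adjusted_rand))

  # two proteins of one marker in the same phage is ambiguous
  dup_map <- rbind(map, data.frame(protein_id = "t7", phage_id = "phage1"))
  expect_error(
    marker_congruence(rbind(pa, part("t7", "B")), pb, dup_map),
    "more than one")
})

test_that("MTase motif scanning reports non-overlapping NPP[YFW] hits", {
  one <- data.frame(protein_id = "p1", sequence = "AANPPYAA",
                    stringsAsFactors = FALSE)
  calls <- scan_mtase_motif(one)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$motif, "NPPY")
  expect_equal(calls$motif_position, 3L)

  none <- data.frame(protein_id = "p2", sequence = "NPPA",
                     stringsAsFactors = FALSE)
  expect_equal(nrow(scan_mtase_motif(none)), 0)

  multi <- data.frame(protein_id = "p3", sequence = "NPPWAAANPPF",
                      stringsAsFactors = FALSE)
  m <- scan_mtase_motif(multi)
  expect_equal(m$motif, c("NPPW", "NPPF"))
  expect_equal(m$motif_position, c(1L, 8L))
})

test_that("planted MTase families are fully detected; decoys follow the analytic rate", {
  withr::with_seed(55, {
    fam <- generate_family(family_spec("MT", paste0("P", 1:10),
                                       ancestor_length = 300,
                                       target_identity = 70,
                                       plant_motif = "NPPW"))
    decoys <- data.frame(
      protein_id = sprintf("D%03d", 1:300), phage_id = "P1",
      product = "hypothetical protein",
      sequence = vapply(rep(300, 300),
                        viromenet:::random_protein_sequence, ""),
      stringsAsFactors = FALSE)
  })
  calls_fam <- scan_mtase_motif(fam)
  expect_setequal(unique(calls_fam$protein_id), fam$protein_id)

  calls_bg <- scan_mtase_motif(decoys)
  sites <- sum(nchar(decoys$sequence) - 3)
  rate <- 3 / 20^4
  # observed background count consistent with the analytic expectation
  expect_gt(stats::poisson.test(nrow(calls_bg), sites * rate)$p.value, 1e-4)
})

test_that("replication proximity is the ordinal CDS distance", {
  withr::with_seed(56, {
    host <- generate_host_with_prophage(
      prophage_spec(prophage_length = 8000, att_repeat_length = 17,
                    gene_layout = c("integrase", "MTase", "lysogeny",
                                    "replication", "terL")),
      flank = 1500)
  })
  cds <- host$features[host$features$kind == "CDS", ]
  mtase_id <- cds$protein_id[cds$product == "adenine DNA methyltransferase"]
  calls <- data.frame(protein_id = mtase_id, motif = "NPPY",
                      motif_position = 10L, stringsAsFactors = FALSE)
  out <- replication_proximity(calls, host$features)
  expect_equal(out$gene_distance_to_replication, 2L)  # layout distance

  # immediately adjacent gene
  adj <- data.frame(protein_id = cds$protein_id[cds$product ==
                                                  "CI repressor protein"],
                    motif = "NPPY", motif_position = 1L,
                    stringsAsFactors = FALSE)
  expect_equal(replication_proximity(adj, host$features)$
                 gene_distance_to_replication, 1L)

  # no replication-labeled gene -> NA, flagged
  no_repl <- host$features[!(host$features$kind == "CDS" &
                               grepl("replication", host$features$product)), ]
  expect_true(is.na(replication_proximity(calls, no_repl)$
                      gene_distance_to_replication))
})
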