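test_that("local alignment matches the independent DP oracle and Biostrings", {
  # frozen worked example, value computed with sw_score_oracle
  hit <- local_align("HEAGAWGHEE", "PAWHEAE")
  expect_equal(hit$raw_score, 17)
  expect_equal(hit$raw_score, sw_score_oracle("HEAGAWGHEE", "PAWHEAE"))

  withr::with_seed(101, {
    for (r in 1:60) {
      q <- random_aa_string(sample(3:12, 1))
      s <- random_aa_string(sample(3:12, 1))
      expect_equal(local_align(q, s)$raw_score, sw_score_oracle(q, s),
                   info = paste(q, s))
    }
  })

  # independent compiled implementation as a second cross-check
  withr::with_seed(102, {
    for (r in 1:10) {
      q <- paste(sample(AA_FULL, 70, TRUE), collapse = "")
      s <- paste(sample(AA_FULL, 85, TRUE), collapse = "")
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(q), Biostrings::AAString(s), type = "local",
        substitutionMatrix = blosum62_matrix, gapOpening = 11,
        gapExtension = 1)
      expect_equal(local_align(q, s)$raw_score, Biostrings::score(pa))
    }
  })
})

test_that("identical sequences align full-length at 100% identity", {
  seq <- strrep("MKTAYIAKQR", 10)
  hit <- local_align(seq, seq)
  expect_equal(hit$identity_pct, 100)
  expect_equal(hit$query_coverage_pct, 100)
  expect_equal(hit$q_start, 1)
  expect_equal(hit$q_end, 100)
})

test_that("disjoint alphabets yield a non-emittable zero alignment", {
  hit <- local_align(strrep("A", 25), strrep("W", 25))
  expect_equal(hit$raw_score, 0)
  expect_equal(hit$identity_pct, 0)
  expect_equal(hit$query_coverage_pct, 0)
  th <- edge_thresholds()
  expect_false(hit$evalue <= th$evalue_max &&
                 hit$identity_pct >= th$identity_min &&
                 hit$query_coverage_pct >= th$coverage_min)
})

test_that("invalid residues are rejected with their position", {
  expect_error(local_align("MKT1AY", "MKTAY"), "position 4")
  expect_error(local_align("MKTAY", "MK-TAY"), "position 3")
})

test_that("bit scores and E-values follow Karlin-Altschul statistics", {
  hit <- local_align(strrep("W", 10), strrep("W", 10))
  # raw score 10 * 11; defaults lambda = 0.267, K = 0.041
  expect_equal(hit$raw_score, 110)
  bit <- (0.267 * 110 - log(0.041)) / log(2)
  expect_equal(hit$bit_score, bit)
  expect_equal(hit$evalue, 100 * 2^(-bit))
})

test_that("score and identity are symmetric; query coverage is not", {
  withr::with_seed(103, {
    a <- paste(sample(AA_FULL, 120, TRUE), collapse = "")
    b <- paste0(a, paste(sample(AA_FULL, 60, TRUE), collapse = ""))
  })
  fwd <- local_align(a, b)
  rev <- local_align(b, a)
  expect_equal(fwd$raw_score, rev$raw_score)
  expect_equal(fwd$identity_pct, rev$identity_pct)
  expect_gt(fwd$query_coverage_pct, rev$query_coverage_pct)
})

test_that("appending unrelated residues to the subject never lowers the score", {
  withr::with_seed(104, {
    for (r in 1:10) {
      q <- paste(sample(AA_FULL, 40, TRUE), collapse = "")
      s <- paste(sample(AA_FULL, 40, TRUE), collapse = "")
      base <- local_align(q, s)$raw_score
      longer <- local_align(q, paste0(s, paste(sample(AA_FULL, 30, TRUE),
                                               collapse = "")))$raw_score
      expect_gte(longer, base)
    }
  })
})

test_that("all_vs_all emits both directed hits per pair, deterministically ordered", {
  proteins <- data.frame(
    protein_id = c("a", "b", "c"), phage_id = "P1",
    product = "hypothetical protein",
    sequence = c(strrep("MKTAYIAKQR", 8), strrep("MKTAYIAKQR", 8),
                 strrep("WGHEEQRNDC", 8)),
    stringsAsFactors = FALSE)
  hits <- all_vs_all(proteins)
  expect_equal(nrow(hits), 6)
  expect_equal(hits$query_id, sort(hits$query_id))
  ab <- hits[hits$query_id == "a" & hits$subject_id == "b", ]
  expect_equal(ab$identity_pct, 100)

  five <- data.frame(
    protein_id = paste0("p", 1:5), phage_id = "P1", product = "holin",
    sequence = strrep("MKTAYIAKQRWGHEE", 10), stringsAsFactors = FALSE)
  h5 <- all_vs_all(five)
  expect_equal(nrow(h5), 20)
  expect_true(all(h5$identity_pct == 100))

  expect_error(all_vs_all(five[c(1, 1), ]), "duplicate")
  expect_error(all_vs_all(five[1, , drop = FALSE]), "at least 2")
})

test_that("all_vs_all passing pairs equal an exhaustive no-prefilter oracle", {
  withr::with_seed(105, {
    cfg <- synth_config(105,
      families = list(family_spec("FA", paste0("P", 1:4), 150, 90),
                      family_spec("FB", paste0("P", 1:3), 180, 90)),
      n_singletons = 3)
    d <- generate_dataset(cfg)
  })
  hits <- all_vs_all(d$proteins)
  th <- edge_thresholds()
  pass <- hits[hits$evalue <= th$evalue_max &
                 hits$identity_pct >= th$identity_min &
                 hits$query_coverage_pct >= th$coverage_min, ]
  got <- sort(paste(pass$query_id, pass$subject_id))

  expected <- character(0)
  ids <- d$proteins$protein_id
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i == j) next
    h <- local_align(d$proteins$sequence[i], d$proteins$sequence[j],
                     query_id = ids[i], subject_id = ids[j])
    if (h$evalue <= th$evalue_max && h$identity_pct >= th$identity_min &&
        h$query_coverage_pct >= th$coverage_min)
      expected <- c(expected, paste(ids[i], ids[j]))
  }
  expect_setequal(got, expected)
})
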