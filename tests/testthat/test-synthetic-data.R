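test_that("generators are pure functions of (parameters, seed)", {
  el <- planted_elements(100L, 250L)
  s1 <- simulate_alignment(length = 400L, elements = el, seed = 77)
  s2 <- simulate_alignment(length = 400L, elements = el, seed = 77)
  expect_identical(s1$alignment$rows, s2$alignment$rows)
  expect_identical(s1$truth$root_sequence, s2$truth$root_sequence)
  s3 <- simulate_alignment(length = 400L, elements = el, seed = 78)
  expect_false(identical(s1$alignment$rows, s3$alignment$rows))

  unit <- s1$truth$root_sequence
  c1 <- simulate_repeat_contigs(unit, seed = 5)
  c2 <- simulate_repeat_contigs(unit, seed = 5)
  expect_identical(c1$contigs, c2$contigs)
  # byte-identical FASTA on two runs
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(setNames(c1$contigs$sequence, c1$contigs$id), f1)
  write_fasta(setNames(c2$contigs$sequence, c2$contigs$id), f2)
  expect_identical(readLines(f1), readLines(f2))

  t1 <- simulate_feature_tracks(s1$truth, seed = 3)
  t2 <- simulate_feature_tracks(s1$truth, seed = 3)
  expect_identical(lapply(t1, `[[`, "intervals"),
                   lapply(t2, `[[`, "intervals"))
})

test_that("zero branch lengths copy the root to every leaf", {
  tree <- parse_newick("((a:0,b:0):0,(c:0,d:0):0);")
  sim <- simulate_alignment(tree, default_model(), length = 300L,
                            elements = default_elements()[0, ], seed = 4)
  expect_true(all(sim$alignment$rows == sim$truth$root_sequence))
  tr <- sliding_similarity(sim$alignment, 50L)
  expect_true(all(tr$values == 1))
})

test_that("pairwise differences match the JC expectation", {
  # two leaves at total distance 0.3: E[diff] = 3/4 (1 - exp(-4*0.3/3))
  tree <- parse_newick("(A:0.15,B:0.15);")
  model <- jc_model(tree)
  p_exp <- 3 / 4 * (1 - exp(-4 * 0.3 / 3))
  n_per <- 10000L
  diffs <- vapply(1:100, function(s) {
    sim <- simulate_alignment(tree, model, length = n_per,
                              elements = default_elements()[0, ], seed = s)
    mean(rdnafoot:::seq_chars(sim$alignment$rows[["A"]]) !=
           rdnafoot:::seq_chars(sim$alignment$rows[["B"]]))
  }, numeric(1))
  p_obs <- mean(diffs)
  se <- sqrt(p_exp * (1 - p_exp) / (100 * n_per))
  expect_lt(abs(p_obs - p_exp), 3 * se)
})

test_that("long-run leaf base frequencies converge to the background", {
  sim <- simulate_alignment(length = 100000L,
                            elements = default_elements()[0, ], seed = 12)
  model <- default_model()
  counts <- table(factor(rdnafoot:::seq_chars(sim$alignment$rows[["marmoset"]]),
                         levels = c("A", "C", "G", "T")))
  pval <- stats::chisq.test(counts, p = model$pi)$p.value
  expect_gt(pval, 0.01)
})

test_that("planted elements are more conserved than background", {
  sim <- simulate_alignment(seed = 42)
  tr <- sliding_similarity(project_to_reference(sim$alignment, "human"))
  el <- sim$truth$elements
  inside <- unlist(lapply(seq_len(nrow(el)), function(i) {
    (el$start[i] + 1L):el$end[i]
  }))
  expect_gt(mean(tr$values[inside]), mean(tr$values[-inside]) + 0.05)
})

test_that("repeat contigs carry copy-number-elevated coverage", {
  set.seed(1)
  unit <- rdnafoot:::random_dna(4000)
  sim <- simulate_repeat_contigs(unit, copy_number = 50L, seed = 8)
  ratio <- mean(sim$contigs$mean_coverage[sim$truth[sim$contigs$id]]) /
    mean(sim$contigs$mean_coverage[!sim$truth[sim$contigs$id]])
  expect_gt(ratio, 45)
  expect_lt(ratio, 55)
  # contigs tile the unit: total repeat-derived bases cover it
  rep_len <- sum(nchar(sim$contigs$sequence[sim$truth[sim$contigs$id]]))
  expect_gte(rep_len, nchar(unit))

  # low copy number with a high threshold is a designed miss
  lo <- simulate_repeat_contigs(unit, copy_number = 2L, seed = 8)
  sel <- select_repeat_contigs(lo$contigs, unit, min_cov_ratio = 5)
  expect_equal(nrow(sel), 0L)
})

test_that("feature tracks are enriched over elements and support zone recovery", {
  # two clusters of elements separated by > max_gap
  el <- planted_elements(start = c(500L, 900L, 1300L, 6000L, 6500L, 7000L),
                         end = c(700L, 1100L, 1500L, 6200L, 6700L, 7200L))
  truth <- list(length = 8000L, elements = el)
  hits <- 0L
  for (s in 1:50) {
    tracks <- simulate_feature_tracks(truth, enrich_prob_in = 0.9,
                                      enrich_prob_out = 0.05, seed = s)
    regions <- genomic_intervals("ref", el$start, el$end,
                                 label = sprintf("c-%d", 1:6))
    zones <- call_zones(regions, tracks, max_gap_bp = 1500L,
                        min_members = 3L, min_cell_lines = 2L)
    spans <- vapply(zones, function(z) c(z$interval$start, z$interval$end),
                    numeric(2))
    for (cl_span in list(c(500L, 1500L), c(6000L, 7200L))) {
      if (length(zones) &&
          any(spans[1, ] < cl_span[2] & spans[2, ] > cl_span[1])) {
        hits <- hits + 1L
      }
    }
  }
  expect_gte(hits / 100, 0.9)  # 2 clusters x 50 seeds

  # null enrichment gives no systematic zone signal
  null_tracks <- simulate_feature_tracks(truth, enrich_prob_in = 0.051,
                                         enrich_prob_out = 0.05, seed = 1)
  expect_error(simulate_feature_tracks(truth, enrich_prob_in = 0.5,
                                       enrich_prob_out = 0.5, seed = 1),
               "enrich_prob")
})

test_that("recovery metrics implement greedy Jaccard matching", {
  truth <- planted_elements(c(100L, 500L), c(200L, 700L))
  exact <- genomic_intervals("ref", truth$start, truth$end,
                             label = c("c-1", "c-2"))
  m <- recovery_metrics(exact, truth)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$precision, 1)
  expect_equal(m$boundary_rmse, 0)

  # shift by 10% of element length: J = 90/110 for the first element
  shifted <- genomic_intervals("ref", c(110L, 520L), c(210L, 720L),
                               label = c("c-1", "c-2"))
  m2 <- recovery_metrics(shifted, truth, match_jaccard = 0.5)
  expect_equal(m2$sensitivity, 1)
  expect_equal(m2$boundary_rmse, sqrt(mean(c(10, 10, 20, 20)^2)))
  # with a threshold above 90/110 the first no longer matches
  m3 <- recovery_metrics(shifted[1, ], truth[1, , drop = FALSE],
                         match_jaccard = 0.85)
  expect_equal(m3$sensitivity, 0)

  empty <- genomic_intervals()
  m4 <- recovery_metrics(empty, truth)
  expect_equal(m4$sensitivity, 0)
  expect_equal(m4$precision, 1.0)
  expect_false(m4$precision_defined)
})
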