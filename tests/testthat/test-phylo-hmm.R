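test_that("pruning likelihood matches closed forms on tiny trees", {
  # single leaf: likelihood reduces to pi
  m1 <- jc_model(parse_newick("A:0.5;"))
  expect_equal(column_log_likelihood(m1, c(A = "A")), log(0.25))
  pi <- c(0.1, 0.4, 0.3, 0.2)
  exch <- matrix(1, 4, 4); diag(exch) <- 0
  m1b <- phylo_model(parse_newick("A:0.5;"), rev_rate_matrix(exch, pi), pi)
  expect_equal(column_log_likelihood(m1b, c(A = "G")), log(0.3))

  # 2-leaf JC, identical bases: 0.25 * (0.25 + 0.75 exp(-4t/3))
  for (t in c(0.1, 0.4, 1)) {
    m2 <- jc_model(parse_newick(sprintf("(A:%g,B:%g);", t / 2, t / 2)))
    expect_equal(column_log_likelihood(m2, c(A = "C", B = "C")),
                 log(0.25 * (0.25 + 0.75 * exp(-4 * t / 3))),
                 tolerance = 1e-10)
  }
})

test_that("pruning equals brute-force enumeration over internal states", {
  model <- toy_rev_model()
  set.seed(11)
  for (k in 1:25) {
    col <- setNames(sample(c("A", "C", "G", "T", "-", "N"), 4, replace = TRUE,
                           prob = c(rep(0.22, 4), 0.06, 0.06)),
                    c("A", "B", "C", "D"))
    if (all(col %in% c("-", "N"))) next
    for (rho in c(1, 0.3)) {
      expect_equal(column_log_likelihood(model, col, rho = rho),
                   log(brute_tree_likelihood(model, col, rho = rho)),
                   tolerance = 1e-10)
    }
  }
})

test_that("pruning agrees with phangorn on a 4-taxon JC column set", {
  skip_if_not_installed("phangorn")
  tree <- toy_tree4()
  model <- jc_model(tree)
  cols <- rbind(A = c("A", "C", "G"), B = c("A", "C", "G"),
                C = c("A", "T", "G"), D = c("A", "C", "C"))
  ll <- column_log_likelihoods(model, cols)
  dat <- phangorn::phyDat(cols, type = "DNA")
  fit <- phangorn::pml(tree, dat)  # pml default is JC
  expect_equal(sum(ll), fit$logLik, tolerance = 1e-6)
})

test_that("tree pruning collapses paths and preserves leaf distances", {
  model <- toy_rev_model()
  pall <- prune_tree_to_rows(model, c("A", "B", "C", "D"))
  expect_equal(sort(pall$tree$tip.label), sort(model$tree$tip.label))
  expect_equal(sum(pall$tree$edge.length), sum(model$tree$edge.length))

  pac <- prune_tree_to_rows(model, c("A", "C"))
  expect_equal(sort(pac$tree$tip.label), c("A", "C"))
  expect_equal(leaf_path_length(pac$tree, "A") + leaf_path_length(pac$tree, "C"),
               0.4)  # 0.15 + 0.25
  p1 <- prune_tree_to_rows(model, "A")
  expect_equal(ape::Ntip(p1$tree), 1L)
  expect_equal(p1$tree$edge.length, 0.15)
  expect_equal(column_log_likelihood(p1, c(A = "C")), log(model$pi[["C"]]))

  expect_error(prune_tree_to_rows(model, c("A", "Z")), "Z")
})

test_that("forward-backward posteriors are proper and match path enumeration", {
  set.seed(3)
  for (rep in 1:5) {
    L <- sample(6:12, 1)
    logemit <- matrix(rnorm(2 * L, sd = 2), 2, L)
    trans <- matrix(c(0.9, 0.1, 0.05, 0.95), 2, 2, byrow = TRUE)
    init <- c(0.3, 0.7)
    fb <- rdnafoot:::forward_backward2(logemit, trans, init)
    expect_equal(fb$loglik, brute_hmm_loglik(logemit, trans, init),
                 tolerance = 1e-9)
    expect_equal(colSums(fb$posterior), rep(1, L), tolerance = 1e-12)
  }
})

test_that("uninformative emissions with a nonconserved prior call nothing", {
  sim <- simulate_alignment(length = 500L, elements = default_elements()[0, ],
                            seed = 5)
  proj <- project_to_reference(sim$alignment, "human")
  model <- default_model()
  cfg <- segmentation_config(rho = 1, target_coverage = 0.05)
  # conserved model identical to nonconserved (rho = 1): posterior must
  # follow the prior, and no region should be called
  seg <- segment_conserved(proj, model, cfg, cons_model = model)
  expect_equal(nrow(seg$regions), 0L)
})

test_that("a planted element is recovered with Jaccard >= 0.7", {
  el <- planted_elements(900L, 1100L, rho = 0.2)
  sim <- simulate_alignment(length = 2000L, elements = el, seed = 42)
  proj <- project_to_reference(sim$alignment, "human")
  seg <- segment_conserved(proj, default_model(),
                           segmentation_config(rho = 0.2))
  expect_equal(nrow(seg$regions), 1L)
  inter <- min(seg$regions$end, 1100) - max(seg$regions$start, 900)
  uni <- max(seg$regions$end, 1100) - min(seg$regions$start, 900)
  expect_gte(inter / uni, 0.7)
  expect_gte(seg$regions$score, 0.5)
  expect_equal(seg$regions$label, "c-1")
})

test_that("conserved calls require a slowed model and peak near the generative rho", {
  # state discrimination comes from the likelihood ratio between the two
  # emission models: with rho near 1 the models coincide and nothing is
  # called; discrimination grows as rho moves away from 1 toward the
  # rate at which the planted elements actually evolved (0.3 here)
  sim <- simulate_alignment(length = 2000L,
                            elements = planted_elements(c(400L, 1200L),
                                                        c(600L, 1500L)),
                            seed = 9)
  proj <- project_to_reference(sim$alignment, "human")
  model <- default_model()
  span <- list(start = 0L, end = 2000L)
  cov <- vapply(c(0.95, 0.8, 0.5, 0.3), function(r) {
    seg <- segment_conserved(proj, model, segmentation_config(rho = r))
    coverage_fraction(seg$regions, span)
  }, numeric(1))
  expect_equal(cov[1], 0)             # near-identical models: no calls
  expect_true(all(diff(cov[1:3]) >= 0))  # coverage grows as rho leaves 1
  planted <- sum(c(200, 300)) / 2000
  expect_gt(cov[4], 0.8 * planted)    # generative rho recovers the truth
  expect_lt(cov[4], 1.5 * planted)
})

test_that("coverage_fraction sums region lengths over the span", {
  span <- list(start = 0L, end = 1000L)
  expect_equal(coverage_fraction(genomic_intervals(), span), 0)
  r1 <- genomic_intervals("ref", c(0L, 500L), c(219L, 500L + 1L), label = c("c-1", "c-2"))
  expect_equal(coverage_fraction(r1, span), 0.22)
  full <- genomic_intervals("ref", 0L, 1000L, label = "c-1")
  expect_equal(coverage_fraction(full, span), 1)
  outside <- genomic_intervals("ref", 900L, 1100L, label = "c-1")
  expect_error(coverage_fraction(outside, span), "outside the span")
})

test_that("regions export as BED with 1000-scaled posterior scores", {
  el <- planted_elements(300L, 500L)
  sim <- simulate_alignment(length = 1000L, elements = el, seed = 2)
  proj <- project_to_reference(sim$alignment, "human")
  seg <- segment_conserved(proj, default_model(), seqname = "human")
  bed <- withr::local_tempfile(fileext = ".bed")
  write_regions_bed(seg, bed)
  x <- read_bed(bed)
  expect_equal(nrow(x), nrow(seg$regions))
  expect_true(all(x$score >= 0 & x$score <= 1000))
  expect_equal(x$label, seg$regions$label)
})
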