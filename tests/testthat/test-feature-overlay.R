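random_intervals <- function(n, L = 10000L, max_w = 300L, labels = "f") {
  s <- sample.int(L - max_w, n)
  w <- sample.int(max_w, n)
  genomic_intervals("ref", s, s + w, label = sprintf("%s%d", labels, seq_len(n)))
}

test_that("region-track intersection equals the brute-force pair check", {
  set.seed(31)
  for (k in 1:5) {
    regions <- random_intervals(100, labels = "c")
    feats <- random_intervals(100, labels = "f")
    hits <- intersect_regions(regions, feature_track(feats, "other"))
    oracle <- brute_overlaps(regions, feats)
    key <- function(r, f) paste(r, f)
    expect_setequal(key(hits$region_label, hits$feature_index),
                    key(regions$label[oracle$region], oracle$feature))
    m <- match(key(regions$label[oracle$region], oracle$feature),
               key(hits$region_label, hits$feature_index))
    expect_equal(hits$overlap_bp[m], oracle$overlap)
    # minimum-overlap filtering agrees too
    hits50 <- intersect_regions(regions, feats, min_overlap_bp = 50L)
    oracle50 <- brute_overlaps(regions, feats, 50L)
    expect_equal(nrow(hits50), nrow(oracle50))
  }
})

test_that("intersection handles empty tracks and rejects mixed sequences", {
  regions <- genomic_intervals("ref", c(0L, 100L), c(50L, 200L),
                               label = c("c-1", "c-2"))
  empty <- feature_track(genomic_intervals(), "transcript")
  expect_equal(nrow(intersect_regions(regions, empty)), 0L)
  expect_equal(unname(overlap_counts(regions, empty)), c(0L, 0L))

  other <- genomic_intervals("chr1", 0L, 50L)
  expect_error(intersect_regions(regions, feature_track(other, "other")),
               "mixed sequence ids")
})

test_that("small-RNA intervals follow the >=5 coverage rule", {
  expect_equal(nrow(small_rna_intervals(rep(4, 50))), 0L)  # all below threshold
  x <- small_rna_intervals(c(0, 5, 5, 4, 6, 6, 6, 0))
  expect_equal(x$start, c(1L, 4L))
  expect_equal(x$end, c(3L, 7L))
  # boundary: exactly 5 qualifies
  y <- small_rna_intervals(c(5, 5, 5))
  expect_equal(nrow(y), 1L)
  expect_equal(c(y$start, y$end), c(0L, 3L))
  # bedGraph-style input
  bg <- genomic_intervals("ref", c(0L, 10L), c(10L, 20L), score = c(7, 2))
  z <- small_rna_intervals(bg)
  expect_equal(c(z$start, z$end), c(0L, 10L))
  expect_error(small_rna_intervals(c(-1, 5)), ">= 0")
})

test_that("small-RNA extraction is local: concatenation equals shifted union", {
  set.seed(33)
  a <- sample(0:8, 40, replace = TRUE)
  b <- sample(0:8, 40, replace = TRUE)
  a[40] <- 0; b[1] <- 0  # avoid a run spanning the junction
  joint <- small_rna_intervals(c(a, b))
  pa <- small_rna_intervals(a)
  pb <- small_rna_intervals(b)
  pb$start <- pb$start + 40L; pb$end <- pb$end + 40L
  expect_equal(joint$start, c(pa$start, pb$start))
  expect_equal(joint$end, c(pa$end, pb$end))
})

test_that("transcript classification puts the FPKM boundary in 'low'", {
  ints <- genomic_intervals("ref", c(0L, 100L, 200L), c(50L, 150L, 250L))
  ints$fpkm <- c(2.0, 0.5, 1.0)
  track <- feature_track(ints, "transcript", "HUVEC")
  cl <- classify_transcripts(track)
  expect_equal(as.character(cl$expression_class), c("expressed", "low", "low"))
  no_fpkm <- feature_track(genomic_intervals("ref", 0L, 10L), "transcript")
  expect_error(classify_transcripts(no_fpkm), "fpkm")
})

zone_fixture <- function() {
  # two clusters of 3 regions each, 5 kb apart; one isolated region
  starts <- c(1000L, 1500L, 2100L, 8000L, 8600L, 9100L, 15000L)
  regions <- genomic_intervals("ref", starts, starts + 200L,
                               label = sprintf("c-%d", 1:7))
  ev <- function(cl) {
    feature_track(genomic_intervals("ref", starts[1:6] - 20L,
                                    starts[1:6] + 220L),
                  "transcript", cl)
  }
  list(regions = regions, tracks = list(ev("CL1"), ev("CL2")))
}

test_that("zones form from evidence-bearing region clusters", {
  fx <- zone_fixture()
  zones <- call_zones(fx$regions, fx$tracks, max_gap_bp = 1500L,
                      min_members = 3L, min_cell_lines = 2L)
  expect_length(zones, 2L)
  expect_equal(zones[[1]]$member_regions, c("c-1", "c-2", "c-3"))
  expect_equal(zones[[2]]$member_regions, c("c-4", "c-5", "c-6"))
  expect_equal(zones[[1]]$interval$start, 1000L)
  expect_equal(zones[[1]]$interval$end, 2300L)
  # zones are sorted and non-overlapping
  expect_lt(zones[[1]]$interval$end, zones[[2]]$interval$start)

  # input order must not matter
  shuf <- fx$regions[sample(7), ]
  zones2 <- call_zones(shuf, fx$tracks, 1500L, 3L, 2L)
  expect_equal(lapply(zones2, `[[`, "member_regions"),
               lapply(zones, `[[`, "member_regions"))

  # evidence in only one cell line is not enough at min_cell_lines = 2
  zones3 <- call_zones(fx$regions, fx$tracks[1], 1500L, 3L, 2L)
  expect_length(zones3, 0L)
  # no evidence at all -> no zones
  none <- feature_track(genomic_intervals(), "transcript", "CL1")
  expect_length(call_zones(fx$regions, list(none), 1500L, 3L, 2L), 0L)
})

test_that("only transcription-associated chromatin states count as evidence", {
  starts <- c(1000L, 1400L, 1900L)
  regions <- genomic_intervals("ref", starts, starts + 100L,
                               label = sprintf("c-%d", 1:3))
  mk_state <- function(states, cl) {
    ints <- genomic_intervals("ref", starts, starts + 100L)
    ints$state <- states
    feature_track(ints, "chromatin_state", cl)
  }
  active <- list(mk_state(c("TSS", "promoter", "enhancer"), "CL1"),
                 mk_state(c("TSS", "TSS", "promoter"), "CL2"))
  expect_length(call_zones(regions, active, 1500L, 3L, 2L), 1L)
  inert <- list(mk_state(rep("CTCF", 3), "CL1"),
                mk_state(rep("CTCF", 3), "CL2"))
  expect_length(call_zones(regions, inert, 1500L, 3L, 2L), 0L)
})

test_that("zone accounting separates known from unknown regions", {
  fx <- zone_fixture()
  known <- feature_track(genomic_intervals("ref", 1000L, 1200L,
                                           label = "promoter"),
                         "known_element")
  zones <- call_zones(fx$regions, fx$tracks, 1500L, 3L, 2L)
  acc <- zone_accounting(zones, fx$regions, known,
                         mapped_labels = c("c-2", "c-5", "c-7"))
  expect_equal(acc$n_regions, 7L)
  expect_equal(acc$known_labels, "c-1")
  expect_equal(acc$n_unknown, 6L)
  expect_equal(sort(acc$unknown_in_zone_labels),
               c("c-2", "c-3", "c-4", "c-5", "c-6"))
  expect_equal(acc$n_unknown_in_zones, 5L)
  expect_equal(acc$n_mapped_unknown_in_zones, 2L)

  # all regions known -> zero unknown in zones
  allk <- feature_track(fx$regions, "known_element")
  acc2 <- zone_accounting(zones, fx$regions, allk)
  expect_equal(acc2$n_unknown_in_zones, 0L)
})

test_that("the packaged known-element annotation loads with promoter elements", {
  ke <- human_known_elements()
  expect_s3_class(ke$intervals, "genomic_intervals")
  labs <- ke$intervals$label
  expect_true(all(c("rRNA_coding", "IGS", "UCE") %in% labs))
  uce <- ke$intervals[labs == "UCE", ]
  expect_equal(uce$end - uce$start, 50L)  # -156..-107 spans 50 bases
  igs <- ke$intervals[labs == "IGS", ]
  expect_equal(igs$end - igs$start, 30615L)
  cod <- ke$intervals[labs == "rRNA_coding", ]
  expect_equal(cod$end - cod$start, 13357L)
})

test_that("Sal-box scanning finds planted terminator motifs on both strands", {
  set.seed(35)
  bg <- rdnafoot:::random_dna(500)
  cons <- "GGGTCGACCAG"
  seqn <- paste0(substr(bg, 1, 100), cons, substr(bg, 112, 300),
                 revcomp(cons), substr(bg, 312, 500))
  hits <- find_sal_boxes(seqn, max_mismatch = 0L)
  expect_gte(nrow(hits), 2L)
  expect_true(any(hits$start == 100L & hits$strand == "+"))
  expect_true(any(hits$start == 300L & hits$strand == "-"))
})
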