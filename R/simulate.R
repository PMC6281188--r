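#' Default primate-like tree and substitution model
#'
#' The default simulation scenario mirrors the geometry of a primate rDNA
#' intergenic-spacer alignment at desk scale: a 7-taxon tree
#' (human..marmoset) with near-neutral IGS-like branch lengths (total tree
#' length 0.5 substitutions/site; human-marmoset distance ~0.3, i.e. ~25%
#' observed divergence) and a GC-rich REV model reflecting rDNA IGS base
#' composition.
#'
#' @return [default_primate_tree()]: an [ape::phylo]; [default_model()]: a
#'   [phylo_model] on that tree.
#' @export
default_primate_tree <- function() {
  parse_newick(paste0(
    "((((((human:0.01,chimp:0.01):0.005,gorilla:0.02):0.015,",
    "orangutan:0.035):0.015,gibbon:0.05):0.04,macaque:0.09):0.06,",
    "marmoset:0.15);"))
}

#' @rdname default_primate_tree
#' @export
default_model <- function() {
  pi <- c(A = 0.2, C = 0.3, G = 0.3, T = 0.2)
  # transition/transversion-biased exchangeabilities (kappa ~ 4)
  exch <- matrix(c(0, 1, 4, 1,
                   1, 0, 1, 4,
                   4, 1, 0, 1,
                   1, 4, 1, 0), 4, 4, byrow = TRUE)
  phylo_model(default_primate_tree(), rev_rate_matrix(exch, pi), pi)
}

#' Planted conserved elements
#'
#' @param start,end 0-based half-open intervals on the root sequence.
#' @param rho branch-length scale inside each element (recycled).
#' @return data.frame of class `planted_elements`.
#' @export
planted_elements <- function(start, end, rho = 0.3) {
  df <- data.frame(start = as.integer(start), end = as.integer(end),
                   rho = rep_len(rho, length(start)))
  df <- df[order(df$start), , drop = FALSE]
  if (nrow(df) > 1L && any(df$start[-1] < head(df$end, -1))) {
    stop_usage("planted elements overlap")
  }
  if (any(df$rho <= 0 | df$rho > 1)) stop_usage("element rho must be in (0, 1]")
  class(df) <- c("planted_elements", "data.frame")
  df
}

#' Default five-element scenario on 5 kb
#'
#' @param rho element branch scale (default 0.3).
#' @return a [planted_elements] data.frame (five elements, 100-300 bp).
#' @export
default_elements <- function(rho = 0.3) {
  planted_elements(start = c(500L, 1400L, 2400L, 3300L, 4300L),
                   end = c(650L, 1700L, 2500L, 3500L, 4550L),
                   rho = rho)
}

# evolve a vector of parent states (1..4) along one branch; P varies by
# site class: classes is an integer vector, Plist[[k]] the matrix for
# class k.
evolve_branch <- function(parent, classes, Plist) {
  child <- integer(length(parent))
  u <- runif(length(parent))
  for (k in seq_along(Plist)) {
    Pc <- Plist[[k]]
    cum <- t(apply(Pc, 1, cumsum))
    sel <- which(classes == k)
    if (!length(sel)) next
    rows <- cum[parent[sel], , drop = FALSE]
    child[sel] <- pmin(1L + rowSums(rows < u[sel]), 4L)
  }
  child
}

#' Simulate an alignment along a tree with planted conserved elements
#'
#' Sites evolve independently down the tree under the model's REV process:
#' the root is drawn from the stationary frequencies and each branch
#' applies `P(t_b)` outside elements and `P(rho * t_b)` inside them.
#' Substitution-only (no indels), so the leaf matrix is already aligned.
#' Bit-reproducible for a given `(parameters, seed)` pair.
#'
#' @param tree an [ape::phylo] (default [default_primate_tree()]).
#' @param model a [phylo_model] (its tree field is ignored; `tree` is
#'   used).
#' @param length sequence length in bp (default 5000).
#' @param elements a [planted_elements] data.frame (default
#'   [default_elements()]).
#' @param seed integer seed.
#' @return list with `alignment` (a [multiple_alignment]) and `truth`
#'   (list: `root_sequence`, `elements`, `leaf_sequences`, `seed`).
#' @export
simulate_alignment <- function(tree = default_primate_tree(),
                               model = default_model(),
                               length = 5000L,
                               elements = default_elements(),
                               seed = 1L) {
  if (nrow(elements) && any(elements$start < 0 | elements$end > length)) {
    stop_usage("elements must lie within [0, length)")
  }
  if (ape::Ntip(tree) < 2L) stop_usage("tree must have >= 2 leaves")
  set.seed(seed, kind = "Mersenne-Twister")
  classes <- rep(1L, length)
  rhos <- 1
  for (i in seq_len(nrow(elements))) {
    classes[(elements$start[i] + 1L):elements$end[i]] <- i + 1L
    rhos <- c(rhos, elements$rho[i])
  }
  tr <- stats::reorder(tree, "cladewise")
  ntip <- ape::Ntip(tr)
  root <- ntip + 1L
  states <- vector("list", ntip + tr$Nnode)
  states[[root]] <- sample.int(4L, length, replace = TRUE, prob = model$pi)
  # cladewise order guarantees parents are simulated before children
  for (e in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[e, 1]; child <- tr$edge[e, 2]
    t_b <- tr$edge.length[e]
    Plist <- lapply(rhos, function(r) transition_matrix(model, r * t_b))
    states[[child]] <- evolve_branch(states[[parent]], classes, Plist)
  }
  leaves <- setNames(lapply(seq_len(ntip), function(i) states[[i]]),
                     tr$tip.label)
  rows <- vapply(leaves, function(s) paste(DNA_BASES[s], collapse = ""),
                 character(1))
  list(alignment = multiple_alignment(rows),
       truth = list(root_sequence = paste(DNA_BASES[states[[root]]],
                                          collapse = ""),
                    elements = elements,
                    leaf_sequences = rows,
                    seed = seed))
}

#' Simulate repeat-unit contigs with copy-number-elevated coverage
#'
#' Emulates the coverage signature of a tandem repeat in a whole-genome
#' assembly: repeat-derived contigs (overlapping fragments tiling the unit,
#' possibly circularly permuted and on random strands) carry mean coverage
#' about `copy_number * base_coverage`, while unique-sequence contigs carry
#' about `base_coverage` (both with ~10% multiplicative noise).
#'
#' @param unit DNA string of the repeat unit.
#' @param copy_number repeat copy number (>= 2).
#' @param n_unique_contigs number of unique background contigs.
#' @param fragment_bp length-2 range for contig lengths.
#' @param base_coverage unique-region coverage (reads/base).
#' @param overlap_bp overlap between consecutive repeat fragments
#'   (default 300).
#' @param seed integer seed.
#' @return list with `contigs` (a [contig_set]) and `truth` (logical
#'   vector: is each contig repeat-derived?).
#' @export
simulate_repeat_contigs <- function(unit, copy_number = 50L,
                                    n_unique_contigs = 20L,
                                    fragment_bp = c(1000L, 2500L),
                                    base_coverage = 10,
                                    overlap_bp = 300L,
                                    seed = 1L) {
  if (copy_number < 2L) stop_usage("copy_number must be >= 2")
  set.seed(seed, kind = "Mersenne-Twister")
  n <- nchar(unit)
  # circular permutation of the unit, then overlapping fragments
  rot <- sample.int(n, 1L) - 1L
  rotated <- paste0(substr(unit, rot + 1L, n), substr(unit, 1L, rot))
  frags <- list()
  pos <- 0L
  while (pos < n) {
    flen <- sample(seq(fragment_bp[1], fragment_bp[2]), 1L)
    end <- min(pos + flen, n)
    frag <- substr(rotated, pos + 1L, end)
    if (runif(1) < 0.5) frag <- revcomp(frag)
    frags[[length(frags) + 1L]] <- frag
    if (end >= n) break
    pos <- end - overlap_bp
  }
  n_rep <- length(frags)
  uniq <- replicate(n_unique_contigs,
                    random_dna(sample(seq(fragment_bp[1], fragment_bp[2]), 1L)))
  seqs <- c(unlist(frags), uniq)
  is_repeat <- c(rep(TRUE, n_rep), rep(FALSE, n_unique_contigs))
  cov <- ifelse(is_repeat, copy_number * base_coverage, base_coverage) *
    exp(rnorm(length(seqs), 0, 0.05))
  ids <- sprintf("contig_%03d", seq_along(seqs))
  ord <- sample(seq_along(seqs))  # shuffle so order carries no signal
  list(contigs = contig_set(ids, seqs[ord], cov[ord]),
       truth = setNames(is_repeat[ord], ids))
}

#' Simulate functional feature tracks enriched over planted elements
#'
#' For each cell line, transcript, CAGE-peak and chromatin-state intervals
#' are placed over each planted element with probability `enrich_prob_in`
#' and over each background tile (500 bp windows between elements) with
#' probability `enrich_prob_out`. Transcript FPKM values are drawn
#' log-normal(meanlog 0.5, sdlog 1); enriched chromatin states are sampled
#' from TSS/promoter/enhancer, background states from CTCF/other.
#'
#' @param truth the `truth` component of [simulate_alignment()] (or any
#'   list with `elements` and a `root_sequence` or `length`).
#' @param enrich_prob_in placement probability over elements (default 0.9).
#' @param enrich_prob_out placement probability per background tile
#'   (default 0.05).
#' @param cell_lines character vector of cell line names.
#' @param seqname sequence name for the intervals.
#' @param seed integer seed.
#' @return list of [feature_track]s (3 per cell line).
#' @export
simulate_feature_tracks <- function(truth,
                                    enrich_prob_in = 0.9,
                                    enrich_prob_out = 0.05,
                                    cell_lines = c("CL1", "CL2", "CL3"),
                                    seqname = "ref",
                                    seed = 1L) {
  if (!(enrich_prob_out >= 0 && enrich_prob_out < enrich_prob_in &&
        enrich_prob_in <= 1)) {
    stop_usage("need 0 <= enrich_prob_out < enrich_prob_in <= 1")
  }
  set.seed(seed, kind = "Mersenne-Twister")
  L <- if (!is.null(truth$root_sequence)) nchar(truth$root_sequence) else truth$length
  el <- truth$elements
  # background tiles: 500 bp windows not overlapping elements
  tiles <- if (L >= 500L) {
    data.frame(start = seq(0L, L - 500L, by = 500L))
  } else {
    data.frame(start = integer())
  }
  tiles$end <- tiles$start + 500L
  if (nrow(el)) {
    keep <- vapply(seq_len(nrow(tiles)), function(i) {
      !any(tiles$start[i] < el$end & el$start < tiles$end[i])
    }, logical(1))
    tiles <- tiles[keep, , drop = FALSE]
  }
  place <- function(prob_slots, starts, ends, jitter = 0) {
    sel <- runif(length(starts)) < prob_slots
    s <- starts[sel]; e <- ends[sel]
    if (jitter > 0 && length(s)) {
      s <- pmax(0L, s - as.integer(runif(length(s), 0, jitter)))
      e <- pmin(L, e + as.integer(runif(length(e), 0, jitter)))
    }
    list(start = s, end = e)
  }
  tracks <- list()
  for (cl in cell_lines) {
    for (ft in c("transcript", "cage_peak", "chromatin_state")) {
      p_in <- place(enrich_prob_in, el$start, el$end, jitter = 100)
      p_out <- place(enrich_prob_out, tiles$start, tiles$end)
      if (ft == "cage_peak") {
        # narrow peaks at the element 5' ends
        p_in$end <- pmin(L, p_in$start + 30L)
        p_out$end <- pmin(L, p_out$start + 30L)
      }
      start <- c(p_in$start, p_out$start)
      end <- c(p_in$end, p_out$end)
      n_in <- length(p_in$start)
      if (!length(start)) {
        ints <- genomic_intervals()
        ints$fpkm <- numeric(0)
        ints$state <- character(0)
      } else {
        ints <- genomic_intervals(seqnames = seqname, start = start,
                                  end = end,
                                  strand = sample(c("+", "-"), length(start),
                                                  replace = TRUE))
        if (ft == "transcript") {
          ints$fpkm <- rlnorm(length(start), meanlog = 0.5, sdlog = 1)
        }
        if (ft == "chromatin_state") {
          ints$state <- c(sample(transcription_states, n_in, replace = TRUE),
                          sample(c("CTCF", "other"),
                                 length(start) - n_in, replace = TRUE))
        }
        ord <- order(ints$start)
        ints <- ints[ord, , drop = FALSE]
        rownames(ints) <- NULL
        class(ints) <- c("genomic_intervals", "data.frame")
      }
      tracks[[length(tracks) + 1L]] <- feature_track(ints, ft, cell_line = cl)
    }
  }
  tracks
}

#' Recovery metrics for called regions against planted truth
#'
#' Greedy one-to-one matching by descending Jaccard index; an element
#' counts as recovered when its best available match has Jaccard >=
#' `match_jaccard`. Precision with zero calls is reported as 1.0 with
#' `precision_defined = FALSE`.
#'
#' @param called [genomic_intervals] of called regions.
#' @param truth a [planted_elements] data.frame (or intervals with
#'   `start`/`end`).
#' @param match_jaccard matching threshold (default 0.5).
#' @return list: `sensitivity`, `precision`, `boundary_rmse` (bp, over
#'   matched pairs; `NA` if none), `n_called`, `n_truth`,
#'   `precision_defined`.
#' @export
recovery_metrics <- function(called, truth, match_jaccard = 0.5) {
  n_c <- nrow(called); n_t <- nrow(truth)
  if (n_t == 0L) stop_usage("empty truth set")
  if (n_c == 0L) {
    return(list(sensitivity = 0, precision = 1.0, boundary_rmse = NA_real_,
                n_called = 0L, n_truth = n_t, precision_defined = FALSE))
  }
  jac <- matrix(0, n_c, n_t)
  for (i in seq_len(n_c)) {
    inter <- pmin(called$end[i], truth$end) - pmax(called$start[i], truth$start)
    inter <- pmax(inter, 0)
    uni <- (called$end[i] - called$start[i]) + (truth$end - truth$start) - inter
    jac[i, ] <- inter / uni
  }
  pairs <- list()
  jw <- jac
  repeat {
    best <- which.max(jw)
    if (jw[best] < match_jaccard || jw[best] <= 0) break
    i <- (best - 1L) %% n_c + 1L
    j <- (best - 1L) %/% n_c + 1L
    pairs[[length(pairs) + 1L]] <- c(i, j)
    jw[i, ] <- -1
    jw[, j] <- -1
    if (length(pairs) == min(n_c, n_t)) break
  }
  n_match <- length(pairs)
  rmse <- if (n_match) {
    errs <- unlist(lapply(pairs, function(p) {
      c(called$start[p[1]] - truth$start[p[2]],
        called$end[p[1]] - truth$end[p[2]])
    }))
    sqrt(mean(errs^2))
  } else NA_real_
  list(sensitivity = n_match / n_t,
       precision = n_match / n_c,
       boundary_rmse = rmse,
       n_called = n_c, n_truth = n_t,
       precision_defined = TRUE)
}
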