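#' Per-column phylogenetic log-likelihoods by Felsenstein pruning
#'
#' Computes `log P(column | tree with branches rho * t_b, Q, pi)` for every
#' column of a leaf-base matrix by the pruning algorithm: partial
#' likelihoods are accumulated post-order, with one 4x4 transition matrix
#' per branch (branch lengths are fixed, so each matrix is computed once and
#' applied to all columns at once). Gaps (`-`) and `N` are treated as
#' missing data (all-ones partial likelihood). Per-node rescaling keeps the
#' computation in range for arbitrarily deep trees.
#'
#' @param model a [phylo_model] whose tree leaves are a subset of the row
#'   names of `leaf_bases`.
#' @param leaf_bases character matrix (rows = leaves, columns = alignment
#'   columns) over `A,C,G,T,N,-`, with rownames.
#' @param rho branch-length scale applied on top of the model's branches
#'   (default 1).
#' @return numeric vector of per-column log-likelihoods.
#' @export
column_log_likelihoods <- function(model, leaf_bases, rho = 1) {
  tree <- model$tree
  tips <- tree$tip.label
  missing <- setdiff(tips, rownames(leaf_bases))
  if (length(missing)) {
    stop_usage("alignment has no row for model leaves: %s",
               paste(missing, collapse = ", "))
  }
  L <- ncol(leaf_bases)
  ntip <- length(tips)
  nnode <- ntip + tree$Nnode
  tr <- if (ntip > 1L) stats::reorder(tree, "postorder") else tree
  # partial likelihood arrays, one 4 x L matrix per node
  partial <- vector("list", nnode)
  logscale <- numeric(L)
  for (i in seq_len(ntip)) {
    code <- encode_bases(leaf_bases[tips[i], ])
    m <- matrix(0, 4, L)
    obs <- !is.na(code)
    m[cbind(code[obs], which(obs))] <- 1
    m[, !obs] <- 1  # missing data: uninformative
    partial[[i]] <- m
  }
  Pmats <- lapply(seq_len(nrow(tr$edge)), function(e) {
    transition_matrix(model, rho * tr$edge.length[e])
  })
  for (e in seq_len(nrow(tr$edge))) {
    parent <- tr$edge[e, 1]
    child <- tr$edge[e, 2]
    contrib <- Pmats[[e]] %*% partial[[child]]
    partial[[parent]] <- if (is.null(partial[[parent]])) contrib
                         else partial[[parent]] * contrib
    mx <- apply(partial[[parent]], 2, max)
    mx[mx == 0] <- 1
    partial[[parent]] <- partial[[parent]] / rep(mx, each = 4)
    logscale <- logscale + log(mx)
  }
  root <- ntip + 1L
  lik <- colSums(model$pi * partial[[root]])
  out <- log(lik) + logscale
  if (any(!is.finite(out))) {
    stop_usage("non-finite column likelihood at column %d",
               which(!is.finite(out))[1])
  }
  out
}

#' @rdname column_log_likelihoods
#' @param column named character vector (leaf -> base) for a single column.
#' @export
column_log_likelihood <- function(model, column, rho = 1) {
  m <- matrix(column, ncol = 1, dimnames = list(names(column), NULL))
  column_log_likelihoods(model, m, rho = rho)
}

#' Segmentation configuration for the conservation HMM
#'
#' Transition probabilities follow the phastCons parameterization: the
#' conserved state is left with probability `mu = 1 / expected_cons_len`
#' and entered with probability `nu = mu * target_coverage /
#' (1 - target_coverage)`, so that the prior fraction of conserved bases is
#' `target_coverage` and conserved segments have prior expected length
#' `expected_cons_len`.
#'
#' @param expected_cons_len prior expected conserved-segment length in bp
#'   (default 45, the published phastCons default).
#' @param target_coverage prior fraction of conserved bases (default 0.3,
#'   the published phastCons default).
#' @param rho branch-length scale of the conserved state when no separate
#'   conserved model is supplied (default 0.3).
#' @param min_region_bp post-filter: called regions shorter than this are
#'   dropped (default 10).
#' @param decode `"viterbi"` (default; region boundaries from the most
#'   probable state path) or `"posterior"` (threshold the posterior).
#' @param posterior_threshold threshold for `decode = "posterior"`.
#' @return a list of class `segmentation_config`.
#' @export
segmentation_config <- function(expected_cons_len = 45,
                                target_coverage = 0.3,
                                rho = 0.3,
                                min_region_bp = 10L,
                                decode = c("viterbi", "posterior"),
                                posterior_threshold = 0.5) {
  decode <- match.arg(decode)
  stopifnot(expected_cons_len > 1, target_coverage > 0, target_coverage < 1,
            rho > 0, rho <= 1, min_region_bp >= 1)
  mu <- 1 / expected_cons_len
  nu <- mu * target_coverage / (1 - target_coverage)
  if (nu >= 1) stop_usage("target_coverage too high for expected_cons_len")
  structure(list(expected_cons_len = expected_cons_len,
                 target_coverage = target_coverage,
                 rho = rho,
                 min_region_bp = as.integer(min_region_bp),
                 decode = decode,
                 posterior_threshold = posterior_threshold,
                 p_stay_conserved = 1 - mu,
                 p_stay_nonconserved = 1 - nu),
            class = "segmentation_config")
}

# scaled forward-backward for a 2-state chain.
# logemit: 2 x L matrix of log emission densities (row 1 = conserved).
# Returns posterior (2 x L), total log-likelihood.
forward_backward2 <- function(logemit, trans, init) {
  L <- ncol(logemit)
  shift <- apply(logemit, 2, max)
  emit <- exp(sweep(logemit, 2, shift))
  alpha <- matrix(0, 2, L)
  beta <- matrix(0, 2, L)
  cvec <- numeric(L)
  a <- init * emit[, 1]
  cvec[1] <- sum(a)
  alpha[, 1] <- a / cvec[1]
  tT <- t(trans)
  for (i in seq_len(L - 1L) + 1L) {
    a <- (tT %*% alpha[, i - 1L])[, 1] * emit[, i]
    cvec[i] <- sum(a)
    alpha[, i] <- a / cvec[i]
  }
  beta[, L] <- 1
  for (i in seq.int(L - 1L, 1L)) {
    b <- trans %*% (emit[, i + 1L] * beta[, i + 1L])
    beta[, i] <- b[, 1] / cvec[i + 1L]
  }
  post <- alpha * beta
  post <- sweep(post, 2, colSums(post), "/")
  list(posterior = post, loglik = sum(log(cvec)) + sum(shift))
}

# Viterbi for a 2-state chain in log space. Ties broken toward state 2
# (nonconserved) by using strict inequality when comparing against it.
viterbi2 <- function(logemit, trans, init) {
  L <- ncol(logemit)
  lt <- log(trans)
  delta <- matrix(-Inf, 2, L)
  psi <- matrix(1L, 2, L)
  delta[, 1] <- log(init) + logemit[, 1]
  for (i in seq_len(L - 1L) + 1L) {
    for (s in 1:2) {
      cand <- delta[, i - 1L] + lt[, s]
      # tie toward nonconserved predecessor (state 2)
      best <- if (cand[1] > cand[2]) 1L else 2L
      delta[s, i] <- cand[best] + logemit[s, i]
      psi[s, i] <- best
    }
  }
  path <- integer(L)
  path[L] <- if (delta[1, L] > delta[2, L]) 1L else 2L
  for (i in seq.int(L - 1L, 1L)) path[i] <- psi[path[i + 1L], i + 1L]
  path
}

#' Segment a projected alignment into conserved regions
#'
#' Runs the two-state (conserved / nonconserved) phylogenetic HMM over the
#' columns of a reference-projected alignment: emissions are per-column
#' phylogenetic likelihoods under the nonconserved model and under the
#' conserved variant (either a separately supplied model, e.g. the
#' conserved `.mod` of a phastCons pair, or the nonconserved model with all
#' branches scaled by `config$rho`). Posteriors come from scaled
#' forward-backward; boundaries from the Viterbi path (or posterior
#' thresholding). Candidate segments shorter than `config$min_region_bp`
#' are dropped and survivors are labelled `c-1`, `c-2`, ... by ascending
#' start.
#'
#' @param proj a [projected_alignment].
#' @param model the nonconserved [phylo_model] (leaves must be alignment
#'   rows; extra alignment rows are ignored, prune the model first if it
#'   has extra leaves).
#' @param config a [segmentation_config].
#' @param cons_model optional conserved [phylo_model]; default
#'   `scale_model(model, config$rho)`.
#' @param seqname sequence name used for the region intervals.
#' @return list of class `conservation_segmentation` with elements
#'   `regions` (a [genomic_intervals] data.frame with `label` = `c-k` and
#'   `score` = mean posterior), `posterior` (per-position P(conserved)),
#'   `loglik`, and `config`.
#' @export
segment_conserved <- function(proj, model, config = segmentation_config(),
                              cons_model = NULL, seqname = NULL) {
  stopifnot(inherits(proj, "projected_alignment"))
  msa <- proj$alignment
  if (msa$n_columns < 2L) stop_usage("alignment too short to segment (< 2 columns)")
  if (is.null(cons_model)) cons_model <- scale_model(model, config$rho)
  mat <- alignment_matrix(msa)
  rownames(mat) <- names(msa$rows)
  ll_n <- column_log_likelihoods(model, mat)
  ll_c <- column_log_likelihoods(cons_model, mat)
  logemit <- rbind(conserved = ll_c, nonconserved = ll_n)
  trans <- matrix(c(config$p_stay_conserved, 1 - config$p_stay_conserved,
                    1 - config$p_stay_nonconserved, config$p_stay_nonconserved),
                  2, 2, byrow = TRUE)
  init <- c(config$target_coverage, 1 - config$target_coverage)
  fb <- forward_backward2(logemit, trans, init)
  post <- fb$posterior[1, ]
  state <- if (config$decode == "viterbi") {
    viterbi2(logemit, trans, init) == 1L
  } else {
    post >= config$posterior_threshold
  }
  segs <- runs_true(state)
  if (nrow(segs)) {
    segs <- segs[segs$end - segs$start >= config$min_region_bp, , drop = FALSE]
  }
  seqname <- seqname %||% proj$reference_id
  if (nrow(segs)) {
    regions <- genomic_intervals(
      seqnames = seqname, start = segs$start, end = segs$end,
      label = paste0("c-", seq_len(nrow(segs))),
      score = vapply(seq_len(nrow(segs)), function(i) {
        mean(post[(segs$start[i] + 1L):segs$end[i]])
      }, numeric(1)))
  } else {
    regions <- genomic_intervals()
  }
  structure(list(regions = regions, posterior = post, loglik = fb$loglik,
                 config = config),
            class = "conservation_segmentation")
}

# maximal runs of TRUE, returned as 0-based half-open intervals.
runs_true <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

#' @export
print.conservation_segmentation <- function(x, ...) {
  cat(sprintf("conservation_segmentation: %d regions, log-likelihood %.2f\n",
              nrow(x$regions), x$loglik))
  invisible(x)
}

#' Fraction of a span covered by conserved regions
#'
#' @param regions a [genomic_intervals] data.frame of called regions.
#' @param span a single-row [genomic_intervals] (or list with `start`,
#'   `end`) delimiting the span (e.g. the IGS).
#' @return sum of region lengths divided by span length.
#' @export
coverage_fraction <- function(regions, span) {
  if (!nrow(regions)) return(0)
  if (is.data.frame(span)) span <- as.list(span[1, ])
  inside <- regions$start >= span$start & regions$end <= span$end
  if (!all(inside)) stop_usage("region %s extends outside the span",
                               regions$label[which(!inside)[1]])
  sum(regions$end - regions$start) / (span$end - span$start)
}

#' Export conserved regions as BED with posterior scores
#'
#' BED score column is `round(1000 * mean_posterior)`.
#'
#' @param seg a `conservation_segmentation`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(seg, path) {
  x <- seg$regions
  lines <- paste(x$seqnames, x$start, x$end, x$label,
                 round(1000 * x$score), x$strand, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
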