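# Independent brute-force oracles used across the suite. These deliberately
# share no code with the implementation paths they check.

# Tree likelihood by exhaustive enumeration over internal-node states.
brute_tree_likelihood <- function(model, column, rho = 1) {
  tree <- model$tree
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  states <- encode_oracle(column[tree$tip.label])
  Pm <- lapply(seq_len(nrow(tree$edge)), function(e) {
    transition_matrix(model, rho * tree$edge.length[e])
  })
  total <- 0
  grid <- as.matrix(expand.grid(rep(list(1:4), nnode)))
  for (g in seq_len(nrow(grid))) {
    assign_all <- c(states, grid[g, ])  # nodes 1..ntip are leaves
    p <- unname(model$pi[grid[g, 1]])   # root is node ntip+1 = first internal
    ok <- TRUE
    for (e in seq_len(nrow(tree$edge))) {
      par <- assign_all[tree$edge[e, 1]]
      chl <- assign_all[tree$edge[e, 2]]
      if (is.na(chl)) next                # missing leaf: sum over its states = 1
      p <- p * Pm[[e]][par, chl]
      if (p == 0) { ok <- FALSE; break }
    }
    if (ok) total <- total + p
  }
  total
}

encode_oracle <- function(bases) {
  match(toupper(bases), c("A", "C", "G", "T"))
}

# HMM total likelihood by exhaustive enumeration over all state paths.
brute_hmm_loglik <- function(logemit, trans, init) {
  L <- ncol(logemit)
  paths <- as.matrix(expand.grid(rep(list(1:2), L)))
  tot <- -Inf
  for (p in seq_len(nrow(paths))) {
    s <- paths[p, ]
    lp <- log(init[s[1]]) + logemit[s[1], 1]
    if (L > 1) {
      for (i in 2:L) lp <- lp + log(trans[s[i - 1], s[i]]) + logemit[s[i], i]
    }
    tot <- max(tot, lp) + log1p(exp(min(tot, lp) - max(tot, lp)))
  }
  tot
}

# Quadratic-space affine-gap local alignment score (Gotoh). A gap of
# length k costs |open| + k * |extend|, matching the package convention.
oracle_local_score <- function(a, b, match = 2, mismatch = -3,
                               open = 5, extend = 2) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  M <- matrix(0, n + 1, m + 1)       # ends in match/mismatch
  X <- matrix(-Inf, n + 1, m + 1)    # gap in b (deletion from a)
  Y <- matrix(-Inf, n + 1, m + 1)    # gap in a
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (ca[i - 1] == cb[j - 1]) match else mismatch
      M[i, j] <- max(0, max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s)
      X[i, j] <- max(M[i - 1, j] - open - extend, X[i - 1, j] - extend)
      Y[i, j] <- max(M[i, j - 1] - open - extend, Y[i, j - 1] - extend)
      best <- max(best, M[i, j])
    }
  }
  best
}

# O(n*m) pairwise interval overlap check.
brute_overlaps <- function(regions, feats, min_overlap = 1L) {
  out <- list()
  for (i in seq_len(nrow(regions))) {
    for (j in seq_len(nrow(feats))) {
      ov <- min(regions$end[i], feats$end[j]) -
        max(regions$start[i], feats$start[j])
      if (ov >= min_overlap) out[[length(out) + 1L]] <- c(i, j, ov)
    }
  }
  if (!length(out)) {
    return(data.frame(region = integer(), feature = integer(),
                      overlap = integer()))
  }
  m <- do.call(rbind, out)
  data.frame(region = m[, 1], feature = m[, 2], overlap = m[, 3])
}

# naive windowed similarity: explicit per-window loop over columns,
# recomputing pair identity from scratch (no prefix sums).
naive_similarity <- function(rows, window, step = 1L) {
  mat <- do.call(rbind, strsplit(rows, ""))
  L <- ncol(mat)
  R <- nrow(mat)
  half_lo <- (window - 1L) %/% 2L
  half_hi <- window - 1L - half_lo
  centers <- seq(1L, L, by = step)
  vapply(centers, function(ctr) {
    lo <- max(1L, ctr - half_lo); hi <- min(L, ctr + half_hi)
    vals <- vapply(lo:hi, function(col) {
      ident <- 0L; tot <- 0L
      for (r1 in 1:(R - 1)) for (r2 in (r1 + 1):R) {
        tot <- tot + 1L
        b1 <- mat[r1, col]; b2 <- mat[r2, col]
        if (b1 == b2 && b1 %in% c("A", "C", "G", "T")) ident <- ident + 1L
      }
      ident / tot
    }, numeric(1))
    mean(vals)
  }, numeric(1))
}

# tiny fixed trees/models shared by tests
toy_tree4 <- function() {
  parse_newick("((A:0.1,B:0.1):0.05,(C:0.2,D:0.2):0.05);")
}

toy_rev_model <- function(tree = toy_tree4()) {
  pi <- c(0.1, 0.4, 0.3, 0.2)
  exch <- matrix(c(0, 2, 5, 1,
                   2, 0, 1, 6,
                   5, 1, 0, 2,
                   1, 6, 2, 0), 4, 4, byrow = TRUE)
  phylo_model(tree, rev_rate_matrix(exch, pi), pi)
}
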