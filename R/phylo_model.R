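#' Phylogenetic substitution model
#'
#' Bundles a rooted tree with branch lengths, a 4x4 reversible rate matrix
#' `Q` (rows sum to zero, base order A,C,G,T), stationary background
#' frequencies `pi`, and a branch-length scale `rho` in (0, 1] that
#' distinguishes the conserved variant of the model: the conserved state of
#' the phylo-HMM uses the same `Q` and `pi` but every branch length
#' multiplied by `rho`.
#'
#' @param tree an [ape::phylo] tree with branch lengths in
#'   substitutions/site.
#' @param Q 4x4 rate matrix (generator); rows must sum to 0 and
#'   off-diagonals be non-negative. For REV models `Q` must satisfy detailed
#'   balance with `pi` (`pi_i Q_ij == pi_j Q_ji`).
#' @param pi background frequency 4-vector (A,C,G,T); renormalized if it
#'   sums to 1 within 1e-6.
#' @param rho branch-length multiplier in (0, 1].
#' @param subst_mod model name (`"REV"`, `"HKY85"` or `"JC69"`), recorded
#'   for `.mod` round trips.
#' @return an object of class `phylo_model`.
#' @seealso [read_mod()], [jc_model()], [transition_matrix()]
#' @export
phylo_model <- function(tree, Q, pi = rep(0.25, 4), rho = 1,
                        subst_mod = "REV") {
  stopifnot(inherits(tree, "phylo"))
  Q <- as.matrix(Q)
  if (!all(dim(Q) == c(4L, 4L))) stop_usage("Q must be 4x4")
  if (any(Q[row(Q) != col(Q)] < -1e-12)) {
    stop_usage("Q off-diagonal entries must be non-negative")
  }
  rs <- rowSums(Q)
  if (max(abs(rs)) > 1e-4) stop_usage("Q rows must sum to 0")
  diag(Q) <- diag(Q) - rs  # absorb rounding from text round trips
  s <- sum(pi)
  if (abs(s - 1) > 1e-6) stop_usage("background frequencies must sum to 1 (got %g)", s)
  pi <- pi / s
  if (any(pi < 0)) stop_usage("background frequencies must be non-negative")
  db <- pi * Q  # detailed balance: pi_i Q_ij symmetric
  if (max(abs(db - t(db))) > 1e-6 * max(abs(Q))) {
    stop_usage("Q does not satisfy detailed balance with pi (not time-reversible)")
  }
  if (!(rho > 0 && rho <= 1)) stop_usage("rho must be in (0, 1]")
  dimnames(Q) <- list(DNA_BASES, DNA_BASES)
  structure(list(tree = tree, Q = Q, pi = setNames(as.numeric(pi), DNA_BASES),
                 rho = rho, subst_mod = subst_mod,
                 eigen = rev_eigen(Q, pi / sum(pi))),
            class = "phylo_model")
}

#' @export
print.phylo_model <- function(x, ...) {
  cat(sprintf("phylo_model: %s, %d leaves, rho = %g\n",
              x$subst_mod, length(x$tree$tip.label), x$rho))
  cat("  pi:", paste(sprintf("%s=%.4f", DNA_BASES, x$pi), collapse = " "), "\n")
  invisible(x)
}

#' Jukes-Cantor model on a tree
#'
#' Convenience constructor: uniform background, equal exchange rates,
#' normalized to one expected substitution per site per unit branch length.
#'
#' @inheritParams phylo_model
#' @return a [phylo_model].
#' @export
jc_model <- function(tree, rho = 1) {
  Q <- matrix(1 / 3, 4, 4)
  diag(Q) <- -1
  phylo_model(tree, Q, rep(0.25, 4), rho = rho, subst_mod = "JC69")
}

#' Construct a REV rate matrix from exchangeabilities
#'
#' `Q[i, j] = s[i, j] * pi[j]` for `i != j`, diagonal set so rows sum to
#' zero, scaled so the expected substitution rate at stationarity is 1.
#'
#' @param exch symmetric 4x4 exchangeability matrix (diagonal ignored).
#' @param pi background frequencies.
#' @return 4x4 rate matrix.
#' @export
rev_rate_matrix <- function(exch, pi) {
  exch <- as.matrix(exch)
  Q <- exch * rep(pi, each = 4)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  rate <- -sum(pi * diag(Q))
  Q / rate
}

# Eigendecomposition of a reversible Q via symmetrization:
# S = D^{1/2} Q D^{-1/2} is symmetric for reversible Q (D = diag(pi)).
# Returns components to build P(t) = D^{-1/2} U exp(L t) U' D^{1/2}.
rev_eigen <- function(Q, pi) {
  sq <- sqrt(pmax(pi, 1e-300))
  S <- (Q * sq) / rep(sq, each = 4)  # diag(sq) %*% Q %*% diag(1/sq)
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  list(left = e$vectors / sq,          # D^{-1/2} U   (4x4, rows scaled)
       right = t(e$vectors * sq),      # U' D^{1/2}
       values = e$values)
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' Computed by eigendecomposition of the symmetrized reversible generator;
#' falls back to series-based [Matrix-free] scaling and squaring if the
#' decomposition is ill-conditioned.
#'
#' @param model a [phylo_model].
#' @param t branch length (already including any `rho` scaling).
#' @return 4x4 stochastic matrix, rows indexed by ancestral base.
#' @export
transition_matrix <- function(model, t) {
  stopifnot(t >= 0)
  ed <- model$eigen %||% rev_eigen(model$Q, model$pi)
  P <- ed$left %*% (exp(ed$values * t) * ed$right)
  if (any(!is.finite(P)) || any(P < -1e-8)) {
    P <- expm_ss(model$Q * t)
  }
  P[P < 0] <- 0
  P / rowSums(P)
}

# scaling-and-squaring matrix exponential (Taylor at scaled argument);
# only used as a fallback for ill-conditioned eigendecompositions.
expm_ss <- function(A, order = 12L) {
  n <- nrow(A)
  s <- max(0L, ceiling(log2(max(1e-300, max(abs(A))))) + 3L)
  As <- A / 2^s
  P <- diag(n)
  term <- diag(n)
  for (k in seq_len(order)) {
    term <- term %*% As / k
    P <- P + term
  }
  for (k in seq_len(s)) P <- P %*% P
  P
}

#' Read a phastCons-style .mod file
#'
#' Parses the key/value dialect used by phastCons model files. Required
#' fields are `SUBST_MOD`, `RATE_MAT` and `TREE`; `BACKGROUND` may be
#' omitted for JC69 (uniform frequencies are assumed). Unknown keys (e.g.
#' `TRAINING_LNL`) are ignored with a warning. `RATE_MAT` rows follow the
#' key on subsequent lines.
#'
#' @param path path to the `.mod` file.
#' @param rho branch-length scale to attach (default 1).
#' @return a [phylo_model].
#' @export
read_mod <- function(path, rho = 1) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- list()
  i <- 1L
  while (i <= length(lines)) {
    line <- lines[i]
    m <- regmatches(line, regexec("^([A-Z_]+):\\s*(.*)$", line))[[1]]
    if (length(m) != 3L) stop_usage(".mod format error at line %d: '%s'", i, line)
    key <- m[2]; val <- trimws(m[3])
    if (key == "RATE_MAT") {
      rows <- list()
      if (nzchar(val)) rows[[1]] <- val
      while (i + 1L <= length(lines) &&
             !grepl("^[A-Z_]+:", lines[i + 1L])) {
        i <- i + 1L
        rows[[length(rows) + 1L]] <- lines[i]
      }
      fields[[key]] <- vapply(rows, identity, character(1))
    } else {
      fields[[key]] <- val
    }
    i <- i + 1L
  }
  known <- c("ALPHABET", "ORDER", "SUBST_MOD", "BACKGROUND", "RATE_MAT",
             "TREE", "NRATECATS")
  unknown <- setdiff(names(fields), known)
  if (length(unknown)) {
    warning(sprintf("ignoring unknown .mod fields: %s",
                    paste(unknown, collapse = ", ")), call. = FALSE)
  }
  if (is.null(fields$TREE)) stop_usage(".mod format error: missing TREE field")
  if (is.null(fields$RATE_MAT)) stop_usage(".mod format error: missing RATE_MAT field")
  subst <- toupper(fields$SUBST_MOD %||% "REV")
  if (!subst %in% c("REV", "HKY85", "JC69")) {
    stop_usage("unsupported substitution model '%s' (supported: REV, HKY85, JC69)", subst)
  }
  pi <- if (!is.null(fields$BACKGROUND)) {
    as.numeric(strsplit(trimws(fields$BACKGROUND), "\\s+")[[1]])
  } else if (subst == "JC69") {
    rep(0.25, 4)
  } else {
    stop_usage(".mod format error: BACKGROUND required for %s", subst)
  }
  if (length(pi) != 4L || anyNA(pi)) stop_usage(".mod format error: BACKGROUND must have 4 values")
  Q <- do.call(rbind, lapply(fields$RATE_MAT, function(r) {
    as.numeric(strsplit(trimws(r), "\\s+")[[1]])
  }))
  if (!all(dim(Q) == c(4L, 4L)) || anyNA(Q)) {
    stop_usage(".mod format error: RATE_MAT must be a 4x4 numeric matrix")
  }
  tree <- parse_newick(fields$TREE)
  phylo_model(tree, Q, pi, rho = rho, subst_mod = subst)
}

#' Write a phastCons-style .mod file
#'
#' @param model a [phylo_model].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mod <- function(model, path) {
  fmt <- function(x) formatC(x, format = "f", digits = 8)
  lines <- c("ALPHABET: A C G T",
             "ORDER: 0",
             paste0("SUBST_MOD: ", model$subst_mod),
             paste0("BACKGROUND: ", paste(fmt(model$pi), collapse = " ")),
             "RATE_MAT:",
             apply(model$Q, 1, function(r) paste(" ", paste(fmt(r), collapse = " "))),
             paste0("TREE: ", ape::write.tree(model$tree)))
  writeLines(lines, path)
  invisible(path)
}

#' Scale every branch of a model by rho
#'
#' Returns the conserved-state variant of a nonconserved model: same rate
#' matrix and background, branch lengths multiplied by `rho < 1`.
#'
#' @param model a [phylo_model].
#' @param rho branch-length multiplier in (0, 1].
#' @return a [phylo_model] with scaled branch lengths and `rho` recorded.
#' @export
scale_model <- function(model, rho) {
  stopifnot(rho > 0, rho <= 1)
  model$tree$edge.length <- model$tree$edge.length * rho
  model$rho <- rho
  model
}
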