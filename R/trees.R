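#' Parse a newick tree
#'
#' Wraps [ape::read.tree()] with the validation the pipeline relies on:
#' balanced parentheses, unique leaf names and non-negative branch lengths.
#' Single-leaf statements such as `"A:1.0;"`, which `ape` does not accept,
#' are handled directly so that degenerate trees (one aligned species) still
#' work.
#'
#' @param text a single newick statement terminated by `";"`.
#' @return an [ape::phylo] tree (rooted; leaf order as encountered).
#' @examples
#' tr <- parse_newick("((A:0.1,B:0.1):0.05,(C:0.2,D:0.2):0.05);")
#' ape::Ntip(tr)
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!endsWith(text, ";")) stop_usage("newick parse error: missing terminal ';'")
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close) {
    stop_usage("newick parse error: unbalanced parentheses (%d '(' vs %d ')')",
               n_open, n_close)
  }
  if (n_open == 0L && !grepl(",", text, fixed = TRUE)) {
    # single-leaf statement "A:1.0;" or "A;"
    body <- sub(";$", "", text)
    parts <- strsplit(body, ":", fixed = TRUE)[[1]]
    bl <- if (length(parts) > 1L) as.numeric(parts[2]) else 0
    if (is.na(bl)) stop_usage("newick parse error: bad branch length '%s'", parts[2])
    if (bl < 0) stop_usage("newick parse error: negative branch length for leaf '%s'", parts[1])
    tr <- structure(list(edge = matrix(c(2L, 1L), 1L, 2L),
                         edge.length = bl, Nnode = 1L,
                         tip.label = parts[1]),
                    class = "phylo", order = "cladewise")
    return(tr)
  }
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr)) stop_usage("newick parse error: could not parse '%s'", text)
  if (anyDuplicated(tr$tip.label)) {
    dup <- tr$tip.label[duplicated(tr$tip.label)][1]
    stop_usage("newick parse error: duplicate leaf name '%s'", dup)
  }
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0)) {
    i <- which(tr$edge.length < 0)[1]
    node <- tr$edge[i, 2]
    lab <- if (node <= ape::Ntip(tr)) tr$tip.label[node] else paste0("node#", node)
    stop_usage("newick parse error: negative branch length (%g) on branch to '%s'",
               tr$edge.length[i], lab)
  }
  if (is.null(tr$edge.length)) tr$edge.length <- rep(0, nrow(tr$edge))
  tr
}

#' Total root-to-leaf path length
#'
#' @param tree an [ape::phylo] tree.
#' @param leaf leaf label.
#' @return numeric path length (substitutions/site).
#' @export
leaf_path_length <- function(tree, leaf) {
  i <- match(leaf, tree$tip.label)
  if (is.na(i)) stop_usage("'%s' is not a leaf of the tree", leaf)
  total <- 0
  node <- i
  root <- ape::Ntip(tree) + 1L
  while (node != root) {
    e <- which(tree$edge[, 2] == node)
    total <- total + tree$edge.length[e]
    node <- tree$edge[e, 1]
  }
  total
}

#' Restrict a phylogenetic model to a set of leaves
#'
#' Removes leaves that are not alignment rows and collapses the resulting
#' unbranched internal nodes, summing their branch lengths (valid under any
#' homogeneous substitution model because P(t1)P(t2) = P(t1+t2)). The rate
#' matrix and background frequencies are unchanged.
#'
#' @param model a [phylo_model].
#' @param row_ids character vector of leaf names to keep.
#' @return the restricted [phylo_model].
#' @export
prune_tree_to_rows <- function(model, row_ids) {
  tree <- model$tree
  missing <- setdiff(row_ids, tree$tip.label)
  if (length(missing)) {
    stop_usage("not a leaf of the model tree: %s",
               paste(missing, collapse = ", "))
  }
  if (length(row_ids) == 1L) {
    bl <- leaf_path_length(tree, row_ids)
    tree2 <- structure(list(edge = matrix(c(2L, 1L), 1L, 2L),
                            edge.length = bl, Nnode = 1L,
                            tip.label = row_ids),
                       class = "phylo", order = "cladewise")
  } else if (setequal(row_ids, tree$tip.label)) {
    tree2 <- tree
  } else {
    tree2 <- ape::keep.tip(tree, row_ids)
  }
  model$tree <- tree2
  model
}
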