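#' Multiple alignment container
#'
#' A multiple alignment is stored as a named character vector of equal-length
#' gapped sequences (alphabet `A,C,G,T,N,-`), wrapped in class
#' `multiple_alignment`. Row order is preserved from the input.
#'
#' @param rows named character vector of gapped sequences.
#' @return an object of class `multiple_alignment`.
#' @export
multiple_alignment <- function(rows) {
  stopifnot(is.character(rows), !is.null(names(rows)), length(rows) >= 2L)
  w <- unique(nchar(rows))
  if (length(w) != 1L) stop_usage("alignment rows have unequal lengths: %s",
                                  paste(unique(nchar(rows)), collapse = ", "))
  if (anyDuplicated(names(rows))) stop_usage("duplicate row names in alignment")
  structure(list(rows = toupper(rows), n_columns = w),
            class = "multiple_alignment")
}

#' @export
print.multiple_alignment <- function(x, ...) {
  cat(sprintf("multiple_alignment: %d rows x %d columns\n",
              length(x$rows), x$n_columns))
  invisible(x)
}

# alignment as a character matrix (rows x columns)
alignment_matrix <- function(msa) {
  do.call(rbind, strsplit(msa$rows, "", fixed = TRUE))
}

#' Read a multiple alignment (aligned FASTA or CLUSTAL)
#'
#' @param path file path.
#' @param format `"fasta"` or `"clustal"`; default guessed from the first
#'   line.
#' @return a [multiple_alignment].
#' @export
read_alignment <- function(path, format = NULL) {
  if (is.null(format)) {
    first <- readLines(path, n = 1L)
    format <- if (startsWith(first, ">")) "fasta" else "clustal"
  }
  aln <- if (format == "fasta") {
    Biostrings::readDNAMultipleAlignment(path, format = "fasta")
  } else {
    Biostrings::readDNAMultipleAlignment(path, format = "clustal")
  }
  rows <- as.character(Biostrings::unmasked(aln))
  multiple_alignment(rows)
}

#' Write an alignment as aligned FASTA
#'
#' @param msa a [multiple_alignment].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(msa, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(msa$rows)) {
    writeLines(c(paste0(">", id), msa$rows[[id]]), con)
  }
  invisible(path)
}

#' Read unaligned FASTA sequences
#'
#' @param path file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write unaligned FASTA sequences
#'
#' @param seqs named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), path, width = 70L)
  invisible(path)
}

#' Project an alignment onto its reference row
#'
#' Drops every alignment column in which the reference row carries a gap, so
#' that remaining columns are in one-to-one correspondence with reference
#' positions. Bidirectional coordinate maps between original alignment
#' columns and reference positions are attached.
#'
#' @param msa a [multiple_alignment].
#' @param reference_id name of the reference row.
#' @return an object of class `projected_alignment` with fields
#'   `alignment` (gap-free reference row), `reference_id`,
#'   `col_to_ref` (original column -> reference position, `NA` for dropped
#'   columns) and `ref_to_col` (reference position -> original column).
#'   All positions 0-based.
#' @examples
#' msa <- multiple_alignment(c(H = "AC-GT", C = "ACAGT", M = "A-AGA"))
#' proj <- project_to_reference(msa, "H")
#' proj$alignment$rows
#' @export
project_to_reference <- function(msa, reference_id) {
  if (!reference_id %in% names(msa$rows)) {
    stop_usage("reference row '%s' is not in the alignment", reference_id)
  }
  ref <- seq_chars(msa$rows[[reference_id]])
  keep <- ref != "-"
  if (!any(keep)) stop_usage("reference row '%s' is all gaps: empty projection",
                             reference_id)
  keep_idx <- which(keep)
  rows <- vapply(msa$rows, function(s) {
    paste(seq_chars(s)[keep_idx], collapse = "")
  }, character(1))
  col_to_ref <- rep(NA_integer_, msa$n_columns)
  col_to_ref[keep_idx] <- seq_along(keep_idx) - 1L
  structure(list(alignment = multiple_alignment(rows),
                 reference_id = reference_id,
                 col_to_ref = col_to_ref,
                 ref_to_col = keep_idx - 1L),
            class = "projected_alignment")
}

#' @export
print.projected_alignment <- function(x, ...) {
  cat(sprintf("projected_alignment: %d rows x %d reference positions (ref '%s')\n",
              length(x$alignment$rows), x$alignment$n_columns, x$reference_id))
  invisible(x)
}

# per-column mean pairwise identity: fraction of row pairs with identical
# non-gap, non-N bases; pairs involving '-' or 'N' count as non-identical.
column_pair_identity <- function(mat) {
  n_rows <- nrow(mat)
  denom <- n_rows * (n_rows - 1) / 2
  ident <- 0
  for (b in DNA_BASES) {
    nb <- colSums(mat == b)
    ident <- ident + nb * (nb - 1) / 2
  }
  ident / denom
}

#' Sliding-window similarity track
#'
#' Similarity at a position is the mean, over the columns of a window
#' centered there, of the fraction of row pairs carrying identical
#' (non-gap, non-N) bases: 0 means no identity, 1 means all bases the same.
#' Pairs involving `-` or `N` are counted as non-identical but remain in the
#' denominator, so indel-rich regions score low. Windows at the track edges
#' are truncated rather than padded, keeping the track the same length as
#' the reference.
#'
#' @param proj a [projected_alignment] (or a [multiple_alignment], e.g. when
#'   no projection is needed).
#' @param window_bp window width in bp (default 50).
#' @param step_bp positions between evaluated window centers (default 1).
#' @return object of class `similarity_track`: list with `positions`
#'   (0-based reference positions), `values` in [0,1], `window_bp`,
#'   `step_bp`.
#' @export
sliding_similarity <- function(proj, window_bp = 50L, step_bp = 1L) {
  msa <- if (inherits(proj, "projected_alignment")) proj$alignment else proj
  stopifnot(inherits(msa, "multiple_alignment"))
  L <- msa$n_columns
  if (window_bp < 1L) stop_usage("window_bp must be >= 1")
  if (window_bp > L) stop_usage("window (%d) larger than alignment (%d)", window_bp, L)
  if (step_bp < 1L) stop_usage("step_bp must be >= 1")
  colsim <- column_pair_identity(alignment_matrix(msa))
  # truncated centered windows via prefix sums
  half_lo <- (window_bp - 1L) %/% 2L
  half_hi <- window_bp - 1L - half_lo
  centers <- seq.int(1L, L, by = step_bp)
  lo <- pmax(1L, centers - half_lo)
  hi <- pmin(L, centers + half_hi)
  cs <- c(0, cumsum(colsim))
  vals <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  vals <- pmin(1, pmax(0, vals))
  structure(list(positions = centers - 1L, values = vals,
                 window_bp = as.integer(window_bp),
                 step_bp = as.integer(step_bp)),
            class = "similarity_track")
}

#' @export
print.similarity_track <- function(x, ...) {
  cat(sprintf("similarity_track: %d positions, window %d bp, step %d bp, mean %.3f\n",
              length(x$values), x$window_bp, x$step_bp, mean(x$values)))
  invisible(x)
}

#' Export a similarity track as bedGraph intervals
#'
#' @param track a `similarity_track`.
#' @param seqname sequence name for the output intervals.
#' @return a [genomic_intervals] data.frame (one row per evaluated position).
#' @export
similarity_as_intervals <- function(track, seqname = "ref") {
  genomic_intervals(seqnames = seqname,
                    start = track$positions,
                    end = track$positions + track$step_bp,
                    score = track$values)
}

#' Export projection coordinate maps as a TSV
#'
#' Writes the original-column to reference-position map (0-based, one row
#' per retained column).
#'
#' @param proj a [projected_alignment].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_projection_map <- function(proj, path) {
  df <- data.frame(alignment_column = proj$ref_to_col,
                   reference_position = seq_along(proj$ref_to_col) - 1L)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
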