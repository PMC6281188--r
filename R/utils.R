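#' @importFrom stats runif rnorm rlnorm setNames
#' @importFrom utils read.table write.table head tail
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement a DNA string
#'
#' Thin wrapper around [Biostrings::reverseComplement()] operating on plain
#' character scalars (the package's working representation for sequences).
#'
#' @param x character scalar over the DNA alphabet (IUPAC codes allowed).
#' @return character scalar, the reverse complement.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Split a sequence string into a character vector of single bases.
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Encode bases as integers 1..4 (A,C,G,T); anything else (gap, N) -> NA.
encode_bases <- function(chars) {
  match(toupper(chars), DNA_BASES)
}

# Draw a random DNA string of length n with base frequencies pi.
random_dna <- function(n, pi = rep(0.25, 4)) {
  paste(sample(DNA_BASES, n, replace = TRUE, prob = pi), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_usage <- function(...) {
  stop(sprintf(...), call. = FALSE)
}
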