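#' Alignment scoring scheme
#'
#' BLAST-like defaults: match +2, mismatch -3, gap open -5, gap extend -2.
#' A gap of length k costs `|gap_open| + k * |gap_extend|`.
#'
#' @param match positive match score.
#' @param mismatch negative mismatch score.
#' @param gap_open,gap_extend negative gap penalties.
#' @return list of class `alignment_scoring`.
#' @export
alignment_scoring <- function(match = 2, mismatch = -3, gap_open = -5,
                              gap_extend = -2) {
  stopifnot(match > 0, mismatch <= 0, gap_open <= 0, gap_extend <= 0)
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "alignment_scoring")
}

subst_matrix <- function(scoring) {
  Biostrings::nucleotideSubstitutionMatrix(match = scoring$match,
                                           mismatch = scoring$mismatch,
                                           baseOnly = FALSE, type = "DNA")
}

aln_stats <- function(aln) {
  p <- as.character(Biostrings::pattern(aln))
  s <- as.character(Biostrings::subject(aln))
  cols <- nchar(p)
  if (cols == 0L) return(list(identity = 0, aln_length = 0L, n_match = 0L))
  cp <- seq_chars(p); cs <- seq_chars(s)
  nm <- sum(cp == cs & cp != "-")
  list(identity = nm / cols, aln_length = cols, n_match = nm)
}

#' Optimal local alignment with affine gaps
#'
#' Smith-Waterman alignment (via [Biostrings::pairwiseAlignment()]) of a
#' query against a target. Identity is the fraction of alignment columns
#' (gap columns included in the denominator) carrying identical bases.
#'
#' @param query,target DNA strings.
#' @param scoring an [alignment_scoring].
#' @return list with `score`, `identity`, `aln_length`, `query_start`,
#'   `query_end`, `target_start`, `target_end` (0-based half-open), and the
#'   aligned strings `query_aln`, `target_aln`.
#' @export
local_align <- function(query, target, scoring = alignment_scoring()) {
  stopifnot(nchar(query) > 0, nchar(target) > 0)
  aln <- Biostrings::pairwiseAlignment(
    toupper(query), toupper(target), type = "local",
    substitutionMatrix = subst_matrix(scoring),
    gapOpening = abs(scoring$gap_open), gapExtension = abs(scoring$gap_extend))
  st <- aln_stats(aln)
  p <- Biostrings::pattern(aln); s <- Biostrings::subject(aln)
  list(score = Biostrings::score(aln),
       identity = st$identity, aln_length = st$aln_length,
       query_start = Biostrings::start(p) - 1L, query_end = Biostrings::end(p),
       target_start = Biostrings::start(s) - 1L, target_end = Biostrings::end(s),
       query_aln = as.character(p), target_aln = as.character(s))
}

#' Map conserved regions onto an outgroup sequence
#'
#' Each region's reference subsequence is locally aligned to the outgroup
#' (and to its reverse complement when `both_strands`); the best-scoring
#' hit is kept. A region is `mapped` when its identity is strictly greater
#' than `min_identity` (the ">50% identity" rule).
#'
#' @param regions [genomic_intervals] of conserved regions on `reference`.
#' @param reference reference DNA string the regions live on.
#' @param outgroup outgroup DNA string.
#' @param min_identity strict lower bound for `mapped` (default 0.5).
#' @param both_strands also search the outgroup minus strand (default TRUE).
#' @param scoring an [alignment_scoring].
#' @return data.frame with one row per region: `region_label`,
#'   `outgroup_start`, `outgroup_end` (0-based half-open on the outgroup
#'   plus strand), `strand`, `identity`, `score`, `mapped`.
#' @export
map_regions_to_outgroup <- function(regions, reference, outgroup,
                                    min_identity = 0.5, both_strands = TRUE,
                                    scoring = alignment_scoring()) {
  n_ref <- nchar(reference)
  out_rc <- if (both_strands) revcomp(outgroup) else NULL
  n_out <- nchar(outgroup)
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    s <- regions$start[i]; e <- regions$end[i]
    if (s < 0 || e > n_ref) {
      stop_usage("region %s is outside the reference (length %d)",
                 regions$label[i], n_ref)
    }
    qseq <- substr(reference, s + 1L, e)
    hit <- local_align(qseq, outgroup, scoring)
    strand <- "+"
    if (both_strands) {
      hit_rc <- local_align(qseq, out_rc, scoring)
      if (hit_rc$score > hit$score) {
        strand <- "-"
        hit <- hit_rc
        ts <- n_out - hit_rc$target_end
        te <- n_out - hit_rc$target_start
        hit$target_start <- ts; hit$target_end <- te
      }
    }
    data.frame(region_label = regions$label[i],
               outgroup_start = hit$target_start,
               outgroup_end = hit$target_end,
               strand = strand,
               identity = hit$identity,
               score = hit$score,
               mapped = hit$identity > min_identity,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Global percent identity between two sequences
#'
#' Needleman-Wunsch global alignment with affine gaps; identity is the
#' fraction of alignment columns with identical bases, reported as a
#' percentage to one decimal. Columns whose coordinate on `a` falls inside
#' an excluded interval (e.g. microsatellite tracts with copy-number
#' variation) are dropped from both numerator and denominator; columns
#' gapped in `a` inherit the coordinate of the preceding `a` base.
#'
#' @param a,b DNA strings.
#' @param exclude optional [genomic_intervals] on `a` to drop.
#' @param scoring an [alignment_scoring].
#' @return percent identity (0-100, one decimal).
#' @export
global_identity <- function(a, b, exclude = NULL,
                            scoring = alignment_scoring()) {
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  aln <- Biostrings::pairwiseAlignment(
    toupper(a), toupper(b), type = "global",
    substitutionMatrix = subst_matrix(scoring),
    gapOpening = abs(scoring$gap_open), gapExtension = abs(scoring$gap_extend))
  ca <- seq_chars(as.character(Biostrings::pattern(aln)))
  cb <- seq_chars(as.character(Biostrings::subject(aln)))
  # 0-based a-coordinate per column; gap-in-a columns inherit previous base
  acoord <- cumsum(ca != "-") - 1L
  keep <- rep(TRUE, length(ca))
  if (!is.null(exclude) && nrow(exclude)) {
    for (i in seq_len(nrow(exclude))) {
      keep <- keep & !(acoord >= exclude$start[i] & acoord < exclude$end[i])
    }
  }
  if (!any(keep)) stop_usage("exclusion covers the entire alignment: identity undefined")
  round(100 * sum(ca[keep] == cb[keep] & ca[keep] != "-") / sum(keep), 1)
}

#' Write ortholog hits as TSV
#'
#' @param hits data.frame from [map_regions_to_outgroup()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ortholog_tsv <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
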