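#' Feature tracks
#'
#' A feature track is a [genomic_intervals] data.frame plus a fixed
#' `feature_type` and the `cell_line` it was measured in. Per-interval
#' attributes (e.g. `fpkm` for transcripts, `state` for chromatin
#' segmentation) are extra columns on the intervals.
#'
#' @param intervals a [genomic_intervals] data.frame (extra columns such as
#'   `fpkm` or `state` allowed).
#' @param feature_type one of `"transcript"`, `"cage_peak"`,
#'   `"chromatin_state"`, `"small_rna_coverage"`, `"known_element"`,
#'   `"orc_peak"`, `"other"`.
#' @param cell_line cell line identifier (may be `""` for cell-line-free
#'   tracks such as known elements).
#' @return list of class `feature_track`.
#' @export
feature_track <- function(intervals,
                          feature_type = c("transcript", "cage_peak",
                                           "chromatin_state",
                                           "small_rna_coverage",
                                           "known_element", "orc_peak",
                                           "other"),
                          cell_line = "") {
  feature_type <- match.arg(feature_type)
  if (!is.null(intervals$fpkm) && any(intervals$fpkm < 0, na.rm = TRUE)) {
    stop_usage("fpkm values must be >= 0")
  }
  structure(list(intervals = intervals, feature_type = feature_type,
                 cell_line = cell_line),
            class = "feature_track")
}

#' @export
print.feature_track <- function(x, ...) {
  cat(sprintf("feature_track: %s%s, %d intervals\n", x$feature_type,
              if (nzchar(x$cell_line)) paste0(" (", x$cell_line, ")") else "",
              nrow(x$intervals)))
  invisible(x)
}

#' Intersect conserved regions with a feature track
#'
#' Overlap is strand-agnostic (conservation is strandless) unless
#' `stranded = TRUE`. Uses interval trees ([IRanges::findOverlaps()]).
#'
#' @param regions [genomic_intervals] of conserved regions.
#' @param track a [feature_track] (or bare [genomic_intervals]).
#' @param min_overlap_bp minimum overlap in bp to count (default 1).
#' @param stranded restrict to same-strand features (default FALSE).
#' @return data.frame with one row per overlapping (region, feature) pair:
#'   `region_label`, `feature_index`, `feature_label`, `overlap_bp`.
#'   Regions with no overlap are absent; use [overlap_counts()] for a
#'   per-region summary including zeros.
#' @export
intersect_regions <- function(regions, track, min_overlap_bp = 1L,
                              stranded = FALSE) {
  feats <- if (inherits(track, "feature_track")) track$intervals else track
  empty <- data.frame(region_label = character(), feature_index = integer(),
                      feature_label = character(), overlap_bp = integer(),
                      stringsAsFactors = FALSE)
  if (!nrow(regions) || !nrow(feats)) return(empty)
  sq <- unique(c(regions$seqnames, feats$seqnames))
  if (length(sq) > 1L) {
    stop_usage("mixed sequence ids in intersection: %s", paste(sq, collapse = ", "))
  }
  ov <- IRanges::findOverlaps(as_iranges(regions), as_iranges(feats),
                              minoverlap = as.integer(min_overlap_bp))
  qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  if (stranded) {
    keep <- regions$strand[qi] == "." | feats$strand[si] == "." |
      regions$strand[qi] == feats$strand[si]
    qi <- qi[keep]; si <- si[keep]
  }
  if (!length(qi)) return(empty)
  obp <- pmin(regions$end[qi], feats$end[si]) -
    pmax(regions$start[qi], feats$start[si])
  data.frame(region_label = regions$label[qi],
             feature_index = si,
             feature_label = feats$label[si],
             overlap_bp = as.integer(obp),
             stringsAsFactors = FALSE)
}

#' Per-region overlap counts against a track
#'
#' @inheritParams intersect_regions
#' @return integer vector, one count per region (named by region label).
#' @export
overlap_counts <- function(regions, track, min_overlap_bp = 1L) {
  hits <- intersect_regions(regions, track, min_overlap_bp)
  counts <- setNames(integer(nrow(regions)), regions$label)
  if (nrow(hits)) {
    tab <- table(hits$region_label)
    counts[names(tab)] <- as.integer(tab)
  }
  counts
}

#' Extract small-RNA intervals from a coverage track
#'
#' Implements the read-coverage rule for calling small-RNA regions:
#' maximal runs of positions with coverage `>= min_cov` (the boundary value
#' itself qualifies) become intervals; runs separated by any position below
#' threshold stay separate.
#'
#' @param coverage either a numeric per-base coverage vector (position i =
#'   base i-1) or a bedGraph-style [genomic_intervals] with `score`.
#' @param min_cov coverage threshold (default 5).
#' @param seqname sequence name for the output (vector input only).
#' @return a [genomic_intervals] data.frame of qualifying runs.
#' @examples
#' small_rna_intervals(c(0, 5, 5, 4, 6, 6, 6, 0))
#' @export
small_rna_intervals <- function(coverage, min_cov = 5, seqname = "ref") {
  if (is.data.frame(coverage)) {
    n <- max(coverage$end)
    vec <- numeric(n)
    for (i in seq_len(nrow(coverage))) {
      idx <- (coverage$start[i] + 1L):coverage$end[i]
      vec[idx] <- vec[idx] + coverage$score[i]
    }
    seqname <- if (nrow(coverage)) coverage$seqnames[1] else seqname
    coverage <- vec
  }
  if (any(coverage < 0)) stop_usage("coverage values must be >= 0")
  runs <- runs_true(coverage >= min_cov)
  if (!nrow(runs)) return(genomic_intervals())
  genomic_intervals(seqnames = seqname, start = runs$start, end = runs$end)
}

#' Classify transcripts by expression level
#'
#' Transcripts with `fpkm` strictly greater than the threshold are
#' `expressed`; all others (including exactly the threshold value) are
#' `low`. This mirrors the usual display convention of FPKM > 1 versus
#' FPKM < 1, with the boundary assigned to `low`.
#'
#' @param transcripts a [feature_track] of type `"transcript"` whose
#'   intervals carry an `fpkm` column.
#' @param fpkm_threshold threshold (default 1).
#' @return the track's intervals with an added `expression_class` factor
#'   (`expressed` / `low`).
#' @export
classify_transcripts <- function(transcripts, fpkm_threshold = 1.0) {
  ints <- if (inherits(transcripts, "feature_track")) transcripts$intervals else transcripts
  if (is.null(ints$fpkm)) stop_usage("transcript track has no fpkm attribute")
  ints$expression_class <- factor(ifelse(ints$fpkm > fpkm_threshold,
                                         "expressed", "low"),
                                  levels = c("expressed", "low"))
  ints
}

transcription_states <- c("TSS", "promoter", "enhancer")

# does this track count as transcription-associated evidence?
evidence_intervals <- function(track) {
  if (track$feature_type %in% c("transcript", "cage_peak")) {
    return(track$intervals)
  }
  if (track$feature_type == "chromatin_state" &&
      !is.null(track$intervals$state)) {
    return(track$intervals[track$intervals$state %in% transcription_states, ,
                           drop = FALSE])
  }
  NULL
}

#' Call transcription-associated zones
#'
#' A conserved region carries transcription evidence when it overlaps a
#' transcript, a CAGE peak, or a TSS/promoter/enhancer chromatin state in
#' at least `min_cell_lines` distinct cell lines. Evidence-bearing regions
#' are single-linkage clustered along the sequence with inter-region gap
#' `<= max_gap_bp`; clusters with at least `min_members` regions become
#' zones spanning their member regions.
#'
#' The zone definition (membership rule, gap, evidence threshold) is an
#' operational construction of this package; reports should treat zone
#' boundaries as descriptive rather than inferential.
#'
#' @param regions [genomic_intervals] of conserved regions (sorted by
#'   start; they are re-sorted defensively).
#' @param tracks list of [feature_track]s.
#' @param max_gap_bp maximum gap between member regions (default 1500).
#' @param min_members minimum regions per zone (default 3).
#' @param min_cell_lines minimum distinct cell lines with evidence
#'   (default 2).
#' @return list of class `zone_set`: each element has `interval`
#'   ([genomic_intervals] row), `member_regions` (labels) and `evidence`
#'   (per cell line counts of evidence overlaps across member regions).
#' @export
call_zones <- function(regions, tracks, max_gap_bp = 1500L,
                       min_members = 3L, min_cell_lines = 2L) {
  out <- structure(list(), class = "zone_set")
  if (!nrow(regions)) return(out)
  regions <- regions[order(regions$start), , drop = FALSE]
  cls <- vapply(tracks, function(t) t$cell_line, character(1))
  evidence_by_cl <- matrix(0L, nrow(regions), length(unique(cls)),
                           dimnames = list(regions$label, unique(cls)))
  for (t in tracks) {
    ev <- evidence_intervals(t)
    if (is.null(ev) || !nrow(ev)) next
    counts <- overlap_counts(regions, ev)
    evidence_by_cl[, t$cell_line] <- evidence_by_cl[, t$cell_line] + counts
  }
  n_cl <- rowSums(evidence_by_cl > 0L)
  has_ev <- n_cl >= min_cell_lines
  idx <- which(has_ev)
  if (!length(idx)) return(out)
  # single-linkage chaining along the sequence
  starts <- regions$start[idx]; ends <- regions$end[idx]
  brk <- c(FALSE, starts[-1] - head(ends, -1) > max_gap_bp)
  cluster <- cumsum(brk)
  zones <- list()
  for (k in unique(cluster)) {
    members <- idx[cluster == k]
    if (length(members) < min_members) next
    zint <- genomic_intervals(seqnames = regions$seqnames[members[1]],
                              start = min(regions$start[members]),
                              end = max(regions$end[members]),
                              label = paste0("zone-", length(zones) + 1L))
    zones[[length(zones) + 1L]] <-
      list(interval = zint,
           member_regions = regions$label[members],
           evidence = colSums(evidence_by_cl[members, , drop = FALSE]))
  }
  structure(zones, class = "zone_set")
}

#' @export
print.zone_set <- function(x, ...) {
  cat(sprintf("zone_set: %d zones\n", length(x)))
  for (z in x) {
    cat(sprintf("  %s: [%d, %d), %d regions (%s..%s)\n",
                z$interval$label, z$interval$start, z$interval$end,
                length(z$member_regions),
                z$member_regions[1], tail(z$member_regions, 1)))
  }
  invisible(x)
}

#' Account for known and unknown conserved regions in zones
#'
#' Splits conserved regions into known (overlapping a known-element track)
#' and unknown, and counts how many unknown regions fall inside zones, with
#' an optional further split by cross-species mapping.
#'
#' @param zones a `zone_set` from [call_zones()].
#' @param regions [genomic_intervals] of conserved regions.
#' @param known_elements a [feature_track] of previously characterized
#'   elements.
#' @param mapped_labels optional character vector of region labels that
#'   mapped to an outgroup (e.g. from [map_regions_to_outgroup()]).
#' @return list with counts: `n_regions`, `n_known`, `n_unknown`,
#'   `n_unknown_in_zones`, `known_labels`, `unknown_in_zone_labels`, and
#'   (when `mapped_labels` given) `n_mapped_unknown_in_zones`.
#' @export
zone_accounting <- function(zones, regions, known_elements,
                            mapped_labels = NULL) {
  known <- names(which(overlap_counts(regions, known_elements) > 0L))
  unknown <- setdiff(regions$label, known)
  in_zones <- unique(unlist(lapply(zones, `[[`, "member_regions")))
  unknown_in_zones <- intersect(unknown, in_zones)
  out <- list(n_regions = nrow(regions),
              n_known = length(known),
              n_unknown = length(unknown),
              n_unknown_in_zones = length(unknown_in_zones),
              known_labels = known,
              unknown_in_zone_labels = unknown_in_zones)
  if (!is.null(mapped_labels)) {
    out$n_mapped_unknown_in_zones <-
      length(intersect(unknown_in_zones, mapped_labels))
  }
  out
}

#' Scan a sequence for terminator (Sal-box) motif matches
#'
#' Finds occurrences of the 11 bp rRNA terminator consensus
#' (`GGGTCGACCAG`) allowing up to `max_mismatch` mismatches, on both
#' strands.
#'
#' @param sequence DNA string.
#' @param consensus motif (default the Sal-box consensus).
#' @param max_mismatch allowed mismatches (default 2).
#' @param seqname sequence name for the output.
#' @return a [genomic_intervals] data.frame of motif hits.
#' @export
find_sal_boxes <- function(sequence, consensus = "GGGTCGACCAG",
                           max_mismatch = 2L, seqname = "ref") {
  subj <- Biostrings::DNAString(toupper(sequence))
  res <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") consensus else revcomp(consensus)
    h <- Biostrings::matchPattern(pat, subj, max.mismatch = max_mismatch)
    if (length(h)) {
      res[[strand]] <- genomic_intervals(
        seqnames = seqname,
        start = Biostrings::start(h) - 1L, end = Biostrings::end(h),
        strand = strand, label = "sal_box")
    }
  }
  if (!length(res)) return(genomic_intervals())
  out <- do.call(rbind, res)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("genomic_intervals", "data.frame")
  out
}

#' Load the packaged human rDNA known-element annotation
#'
#' Returns the known-element track shipped with the package: the rRNA
#' promoter control elements (UCE at -156..-107 and CCE at -45..+18
#' relative to the transcription start, mapped onto a unit whose position 0
#' is the transcription start), the coding-region and IGS spans of the
#' 43,972 bp human unit, and the terminator consensus annotation. See the
#' GFF3 comments for the provenance of each record.
#'
#' @return a [feature_track] of type `"known_element"`.
#' @export
human_known_elements <- function() {
  path <- system.file("extdata", "human_rdna_known_elements.gff3",
                      package = "rdnafoot", mustWork = TRUE)
  g <- read_gff3(path)
  feature_track(g, feature_type = "known_element")
}
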