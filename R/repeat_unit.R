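#' Contig records
#'
#' @param id character vector of contig names.
#' @param sequence character vector of DNA sequences.
#' @param mean_coverage numeric vector of mean read coverages (reads/base).
#' @return data.frame of class `contig_set`.
#' @export
contig_set <- function(id, sequence, mean_coverage) {
  stopifnot(length(id) == length(sequence),
            length(id) == length(mean_coverage),
            all(nchar(sequence) > 0), all(is.finite(mean_coverage)),
            all(mean_coverage >= 0))
  df <- data.frame(id = as.character(id), sequence = toupper(sequence),
                   mean_coverage = as.numeric(mean_coverage),
                   stringsAsFactors = FALSE)
  class(df) <- c("contig_set", "data.frame")
  df
}

#' Read a contig coverage TSV
#'
#' Two columns: contig id and mean coverage, no header.
#'
#' @param fasta_path contig FASTA.
#' @param cov_path coverage TSV path.
#' @return a [contig_set].
#' @export
read_contigs <- function(fasta_path, cov_path) {
  seqs <- read_fasta(fasta_path)
  cov <- read.table(cov_path, sep = "\t", header = FALSE,
                    col.names = c("id", "mean_coverage"),
                    stringsAsFactors = FALSE)
  m <- match(names(seqs), cov$id)
  if (anyNA(m)) stop_usage("no coverage for contig '%s'", names(seqs)[which(is.na(m))[1]])
  contig_set(names(seqs), unname(seqs), cov$mean_coverage[m])
}

# best local alignment of a contig to the seed on either strand.
# Returns list(score, identity, aln_length, seed_start, seed_end, strand,
# contig_start, contig_end); coordinates 0-based half-open on the inputs.
seed_hit <- function(contig, seed, scoring = alignment_scoring()) {
  fwd <- local_align(contig, seed, scoring)
  rev <- local_align(revcomp(contig), seed, scoring)
  if (rev$score > fwd$score) {
    n <- nchar(contig)
    list(score = rev$score, identity = rev$identity,
         aln_length = rev$aln_length, strand = "-",
         seed_start = rev$target_start, seed_end = rev$target_end,
         contig_start = n - rev$query_end, contig_end = n - rev$query_start)
  } else {
    c(list(strand = "+",
           seed_start = fwd$target_start, seed_end = fwd$target_end,
           contig_start = fwd$query_start, contig_end = fwd$query_end),
      fwd[c("score", "identity", "aln_length")])
  }
}

#' Select repeat-derived contigs by coverage and seed homology
#'
#' Repeat units present in hundreds of copies per genome assemble into
#' contigs whose read coverage exceeds that of unique regions by roughly
#' the copy number. Contigs are kept when their mean coverage is at least
#' `min_cov_ratio` times the median coverage of all contigs *and* they have
#' a local alignment to the seed sequence at identity >=
#' `min_seed_identity` over >= 200 bp (either strand).
#'
#' @param contigs a [contig_set].
#' @param seed seed DNA sequence (e.g. a known repeat unit from a related
#'   species), length >= 200 bp.
#' @param min_cov_ratio coverage threshold as a multiple of the median
#'   contig coverage (default 5).
#' @param min_seed_identity minimum local-alignment identity to the seed
#'   (default 0.8).
#' @param min_seed_span minimum alignment span in bp (default 200).
#' @return the selected rows of `contigs`, ordered by descending coverage.
#' @export
select_repeat_contigs <- function(contigs, seed, min_cov_ratio = 5,
                                  min_seed_identity = 0.8,
                                  min_seed_span = 200L) {
  if (!nrow(contigs)) stop_usage("empty contig set")
  if (nchar(seed) < 200L) stop_usage("seed must be >= 200 bp")
  med <- stats::median(contigs$mean_coverage)
  highcov <- contigs$mean_coverage >= min_cov_ratio * med
  homologous <- vapply(contigs$sequence, function(s) {
    h <- seed_hit(s, seed)
    h$aln_length >= min_seed_span && h$identity >= min_seed_identity
  }, logical(1), USE.NAMES = FALSE)
  out <- contigs[highcov & homologous, , drop = FALSE]
  out <- out[order(-out$mean_coverage), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("contig_set", "data.frame")
  out
}

#' Repeat unit sequence
#'
#' @param sequence the unit DNA.
#' @param coding_interval,igs_interval [genomic_intervals] rows partitioning
#'   the unit into the rRNA coding region and the intergenic spacer; may be
#'   `NULL` when no annotation has been transferred yet.
#' @param source free-text provenance.
#' @return object of class `repeat_unit`.
#' @export
repeat_unit <- function(sequence, coding_interval = NULL,
                        igs_interval = NULL, source = "") {
  n <- nchar(sequence)
  if (!is.null(coding_interval) && !is.null(igs_interval)) {
    w <- sum(coding_interval$end - coding_interval$start) +
      sum(igs_interval$end - igs_interval$start)
    if (w != n) stop_usage("coding + IGS intervals (%d bp) do not partition the %d bp unit", w, n)
  }
  structure(list(sequence = toupper(sequence), unit_length = n,
                 coding_interval = coding_interval,
                 igs_interval = igs_interval, source = source),
            class = "repeat_unit")
}

#' @export
print.repeat_unit <- function(x, ...) {
  cat(sprintf("repeat_unit: %d bp%s\n", x$unit_length,
              if (nzchar(x$source)) paste0(" (", x$source, ")") else ""))
  invisible(x)
}

# fraction of mismatching bases between two equal-length strings
mismatch_frac <- function(a, b) {
  ca <- seq_chars(a); cb <- seq_chars(b)
  mean(ca != cb)
}

# find overlap length between suffix of `left` and prefix of `right`:
# try `expected` first, then nearby lengths, then scan all >= min_overlap.
# Returns the longest overlap with mismatch fraction <= tol, or 0.
find_overlap <- function(left, right, expected, min_overlap, tol) {
  nmax <- min(nchar(left), nchar(right))
  cand <- unique(pmin(pmax(c(expected + seq(-25L, 25L), nmax:min_overlap),
                           min_overlap), nmax))
  cand <- cand[cand >= min_overlap]
  cand <- cand[order(-(cand == expected), abs(cand - expected))]
  for (k in cand) {
    sfx <- substr(left, nchar(left) - k + 1L, nchar(left))
    pfx <- substr(right, 1L, k)
    if (mismatch_frac(sfx, pfx) <= tol) return(k)
  }
  0L
}

#' Orient and merge selected contigs into a repeat unit
#'
#' Each contig is aligned to the seed (both strands) to fix its orientation
#' and position; contigs are then ordered along the seed and merged across
#' exact or near-exact suffix/prefix overlaps of at least `min_overlap` bp.
#' The result is rotation-normalized so that position 0 of the unit is the
#' seed's position 0 whenever the seed origin is covered; since tandem
#' repeat units are circular, any rotation of the truth is an equally valid
#' reconstruction.
#'
#' @param selected a [contig_set] of repeat-derived contigs.
#' @param seed seed DNA used for orientation and ordering.
#' @param min_overlap minimum merge overlap in bp (default 30).
#' @param max_mismatch tolerated mismatch fraction inside an overlap
#'   (default 0.02).
#' @return a [repeat_unit].
#' @export
orient_and_merge <- function(selected, seed, min_overlap = 30L,
                             max_mismatch = 0.02) {
  if (!nrow(selected)) stop_usage("no contigs to merge")
  n_seed <- nchar(seed)
  hits <- lapply(selected$sequence, seed_hit, seed = seed)
  oriented <- unname(mapply(function(s, h) {
    if (h$strand == "-") revcomp(s) else s
  }, selected$sequence, hits))
  # anchor each contig at its implied seed offset (seed position of the
  # alignment start minus the contig position of the alignment start);
  # offsets of fragments spanning the circular origin come out mod n_seed
  offs <- vapply(seq_along(hits), function(i) {
    h <- hits[[i]]
    cs <- if (h$strand == "-") nchar(oriented[i]) - h$contig_end else h$contig_start
    (h$seed_start - cs) %% n_seed
  }, numeric(1))
  ord <- order(offs)
  oriented <- oriented[ord]
  offs <- offs[ord]
  m <- length(oriented)
  # chain fragments in circular order, trying each cyclic rotation of the
  # order (the tiling may cross the unit origin at one point)
  attempt <- function(idx) {
    merged <- oriented[idx[1]]
    for (i in idx[-1]) {
      k <- find_overlap(merged, oriented[i],
                        as.integer(max(min_overlap,
                                       nchar(merged) -
                                         ((offs[i] - offs[idx[1]]) %% n_seed))),
                        min_overlap, max_mismatch)
      if (k == 0L) return(NULL)
      merged <- paste0(merged, substr(oriented[i], k + 1L, nchar(oriented[i])))
    }
    merged
  }
  merged <- NULL
  merged_off <- 0
  for (k in 0:(m - 1)) {
    idx <- if (k == 0L) seq_len(m) else c((k + 1L):m, seq_len(k))
    merged <- attempt(idx)
    if (!is.null(merged)) {
      merged_off <- offs[idx[1]]
      break
    }
  }
  if (is.null(merged)) {
    gaps <- (offs[c(2:m, 1)] - offs) %% n_seed -
      vapply(oriented, nchar, integer(1))
    j <- which.max(gaps)
    stop_usage(paste0("cannot merge: no overlap between contigs; ",
                      "uncovered seed interval approximately [%d, %d)"),
               as.integer((offs[j] + nchar(oriented[j])) %% n_seed),
               as.integer(offs[c(2:m, 1)][j]))
  }
  # rotation normalization: make position 0 of the unit the seed's
  # position 0 when the seed origin is covered by the merge
  L <- nchar(merged)
  rot <- as.integer((L - merged_off %% L) %% L)
  if (rot > 0 && merged_off + L > n_seed) {
    merged <- paste0(substr(merged, rot + 1L, L), substr(merged, 1L, rot))
  }
  repeat_unit(merged, source = "orient_and_merge")
}

#' In-silico restriction/homing-enzyme digest
#'
#' Finds all exact occurrences of the recognition site and returns the
#' fragment lengths. The cut is placed at the first base of the recognition
#' site. A circular molecule with a single site yields one fragment of the
#' full unit length (the basis of sizing tandem repeat units with a
#' once-per-unit homing enzyme such as I-PpoI).
#'
#' @param unit a [repeat_unit] or DNA string.
#' @param recognition_site non-degenerate DNA recognition sequence.
#' @param circular treat the molecule as circular (default `FALSE`).
#' @return integer vector of fragment lengths (bp); zero sites give one
#'   fragment equal to the molecule length.
#' @examples
#' in_silico_digest("AAAGAATTCAAAGAATTCAA", "GAATTC")
#' @export
in_silico_digest <- function(unit, recognition_site, circular = FALSE) {
  seq <- if (inherits(unit, "repeat_unit")) unit$sequence else toupper(unit)
  site <- toupper(recognition_site)
  if (grepl("[^ACGT]", site)) stop_usage("recognition site must be non-degenerate (A/C/G/T)")
  n <- nchar(seq)
  subject <- if (circular) paste0(seq, substr(seq, 1L, nchar(site) - 1L)) else seq
  hits <- Biostrings::matchPattern(site, Biostrings::DNAString(subject))
  cuts <- Biostrings::start(hits) - 1L   # 0-based cut positions
  cuts <- sort(unique(cuts[cuts < n]))
  if (!length(cuts)) return(n)
  if (circular) {
    if (length(cuts) == 1L) return(n)
    diff(c(cuts, cuts[1] + n))
  } else {
    frags <- diff(c(0L, cuts, n))
    frags[frags > 0L]
  }
}

#' In-silico PCR with exact primer binding
#'
#' Locates exact matches of the forward primer on the template plus strand
#' and of the reverse primer on the minus strand (i.e. of its reverse
#' complement on the plus strand). A product spans from the first base of a
#' forward-primer site to the last base of a reverse-primer
#' reverse-complement site; the reported length is the inclusive span
#' (`end - start` under the half-open convention). All products no longer
#' than `max_product` are returned, sorted by position.
#'
#' Note on conventions: for the classic human 18S probe primers, U13369
#' coordinates 4,328-4,922 span 595 bases inclusively although the source
#' literature quotes a 594 bp product; this function reports the inclusive
#' span (595 for that amplicon) and leaves the off-by-one to the caller's
#' interpretation.
#'
#' @param template DNA string.
#' @param fwd_primer,rev_primer primer sequences, >= 15 bp each; the
#'   reverse primer is given 5'->3' on the minus strand as usual.
#' @param max_product maximum product length (default 5000).
#' @return data.frame with columns `start`, `end` (0-based half-open on the
#'   template) and `length`; zero rows when no product forms.
#' @export
in_silico_pcr <- function(template, fwd_primer, rev_primer,
                          max_product = 5000L) {
  template <- toupper(template)
  if (nchar(fwd_primer) < 15L || nchar(rev_primer) < 15L) {
    stop_usage("primers must be >= 15 bp")
  }
  subj <- Biostrings::DNAString(template)
  fhits <- Biostrings::start(Biostrings::matchPattern(toupper(fwd_primer), subj)) - 1L
  rsite <- revcomp(rev_primer)
  rh <- Biostrings::matchPattern(rsite, subj)
  rends <- Biostrings::end(rh)  # 1-based inclusive end == 0-based half-open end
  empty <- data.frame(start = integer(), end = integer(), length = integer())
  if (!length(fhits) || !length(rends)) return(empty)
  prods <- expand.grid(start = fhits, end = rends)
  prods <- prods[prods$end - prods$start >= nchar(fwd_primer) + nchar(rev_primer) &
                   prods$end - prods$start <= max_product, , drop = FALSE]
  if (!nrow(prods)) return(empty)
  prods$length <- prods$end - prods$start
  prods <- prods[order(prods$start, prods$end), , drop = FALSE]
  rownames(prods) <- NULL
  prods
}
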