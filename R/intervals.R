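#' Genomic intervals
#'
#' The package's interval container is a plain `data.frame` with columns
#' `seqnames`, `start`, `end`, `strand`, `label`, `score`. Coordinates are
#' **0-based half-open** throughout the package (the BED convention);
#' conversion to and from 1-based inclusive systems happens only at I/O
#' boundaries (GFF3) and in user-facing region reports.
#'
#' @param seqnames character vector of sequence identifiers.
#' @param start,end integer vectors, 0-based half-open (`start < end`).
#' @param strand character vector over `{"+", "-", "."}`.
#' @param label character vector of interval names (`NA` allowed).
#' @param score numeric vector of scores (`NA` allowed).
#' @return a `data.frame` of class `genomic_intervals`.
#' @examples
#' genomic_intervals("rDNA", 100, 200, label = "c-1")
#' @export
genomic_intervals <- function(seqnames = character(), start = integer(),
                              end = integer(), strand = ".",
                              label = NA_character_, score = NA_real_) {
  n <- max(length(seqnames), length(start), length(end))
  if (n == 0L) {
    df <- data.frame(seqnames = character(), start = integer(),
                     end = integer(), strand = character(),
                     label = character(), score = numeric(),
                     stringsAsFactors = FALSE)
    class(df) <- c("genomic_intervals", "data.frame")
    return(df)
  }
  df <- data.frame(seqnames = rep_len(as.character(seqnames), n),
                   start = rep_len(as.integer(start), n),
                   end = rep_len(as.integer(end), n),
                   strand = rep_len(as.character(strand), n),
                   label = rep_len(as.character(label), n),
                   score = rep_len(as.numeric(score), n),
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  class(df) <- c("genomic_intervals", "data.frame")
  df
}

validate_intervals <- function(df) {
  bad <- which(!(df$start >= 0L & df$start < df$end))
  if (length(bad)) {
    stop_usage("invalid interval at row %d: start=%d end=%d (need 0 <= start < end)",
               bad[1], df$start[bad[1]], df$end[bad[1]])
  }
  badstrand <- which(!df$strand %in% c("+", "-", "."))
  if (length(badstrand)) {
    stop_usage("invalid strand '%s' at row %d", df$strand[badstrand[1]],
               badstrand[1])
  }
  invisible(df)
}

interval_widths <- function(df) df$end - df$start

# IRanges view of an interval data.frame (1-based inclusive internally to
# IRanges; the 0-based half-open [s, e) maps to IRanges [s+1, e]).
as_iranges <- function(df) {
  IRanges::IRanges(start = df$start + 1L, end = df$end)
}

#' Read interval files (BED, GFF3, bedGraph)
#'
#' All dialects are returned in the package's 0-based half-open convention:
#' BED coordinates are kept as-is, GFF3 1-based inclusive coordinates are
#' converted (`start - 1`, `end`), and bedGraph rows become score-bearing
#' intervals.
#'
#' @param path file path.
#' @param dialect one of `"BED"`, `"GFF3"`, `"bedGraph"`.
#' @return a [genomic_intervals] data.frame. GFF3 adds columns `source`,
#'   `type` and `attributes`.
#' @export
read_intervals <- function(path, dialect = c("BED", "GFF3", "bedGraph")) {
  dialect <- match.arg(dialect)
  switch(dialect,
         BED = read_bed(path),
         GFF3 = read_gff3(path),
         bedGraph = read_bedgraph(path))
}

read_lines_nocomment <- function(path, comment = "#") {
  x <- readLines(path, warn = FALSE)
  x <- x[nzchar(x)]
  x[!startsWith(x, comment)]
}

#' @rdname read_intervals
#' @export
read_bed <- function(path) {
  lines <- read_lines_nocomment(path)
  lines <- lines[!startsWith(lines, "track") & !startsWith(lines, "browser")]
  if (!length(lines)) return(genomic_intervals())
  f <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 3L)) {
    stop_usage("BED line %d has fewer than 3 fields",
               which(nf < 3L)[1])
  }
  get <- function(i, default) {
    vapply(f, function(r) if (length(r) >= i) r[i] else default, character(1))
  }
  start <- as.integer(get(2, NA))
  end <- as.integer(get(3, NA))
  bad <- which(is.na(start) | is.na(end) | start >= end)
  if (length(bad)) {
    stop_usage("BED line %d: invalid coordinates (start >= end or non-numeric)",
               bad[1])
  }
  genomic_intervals(seqnames = get(1, NA),
                    start = start, end = end,
                    label = get(4, NA_character_),
                    score = suppressWarnings(as.numeric(get(5, NA_character_))),
                    strand = ifelse(get(6, ".") %in% c("+", "-"), get(6, "."), "."))
}

#' @rdname read_intervals
#' @export
read_gff3 <- function(path) {
  lines <- read_lines_nocomment(path)
  if (!length(lines)) {
    out <- genomic_intervals()
    out$source <- character()
    out$type <- character()
    out$attributes <- character()
    return(out)
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 9L)) stop_usage("GFF3 line %d has fewer than 9 fields", which(nf < 9L)[1])
  m <- do.call(rbind, f)
  start1 <- as.integer(m[, 4])
  end1 <- as.integer(m[, 5])
  bad <- which(is.na(start1) | is.na(end1) | start1 > end1)
  if (length(bad)) {
    stop_usage("GFF3 line %d: invalid coordinates start=%s end=%s",
               bad[1], m[bad[1], 4], m[bad[1], 5])
  }
  attrs <- m[, 9]
  out <- genomic_intervals(seqnames = m[, 1],
                           start = start1 - 1L, end = end1,
                           strand = ifelse(m[, 7] %in% c("+", "-"), m[, 7], "."),
                           label = gff3_attr(attrs, "ID"),
                           score = suppressWarnings(as.numeric(ifelse(m[, 6] == ".", NA, m[, 6]))))
  out$source <- m[, 2]
  out$type <- m[, 3]
  out$attributes <- attrs
  out
}

gff3_attr <- function(attributes, key) {
  pat <- paste0("(?:^|;)\\s*", key, "=([^;]*)")
  m <- regmatches(attributes, regexec(pat, attributes))
  vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_,
         character(1))
}

#' @rdname read_intervals
#' @export
read_bedgraph <- function(path) {
  lines <- read_lines_nocomment(path)
  lines <- lines[!startsWith(lines, "track")]
  if (!length(lines)) return(genomic_intervals())
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 4L)) {
    stop_usage("bedGraph line %d has fewer than 4 fields", which(lengths(f) < 4L)[1])
  }
  m <- do.call(rbind, f)
  start <- as.integer(m[, 2]); end <- as.integer(m[, 3])
  bad <- which(is.na(start) | is.na(end) | start >= end)
  if (length(bad)) stop_usage("bedGraph line %d: invalid coordinates", bad[1])
  genomic_intervals(seqnames = m[, 1], start = start, end = end,
                    score = as.numeric(m[, 4]))
}

#' Write interval files
#'
#' Deterministic writers for BED (4-6 column), GFF3 and bedGraph. Scores are
#' formatted with 6 decimals so that a write/read round trip preserves them.
#'
#' @param x a [genomic_intervals] data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  label <- ifelse(is.na(x$label), ".", x$label)
  score <- ifelse(is.na(x$score), "0", formatC(x$score, format = "f", digits = 6))
  lines <- paste(x$seqnames, x$start, x$end, label, score, x$strand, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_bed
#' @param source,type GFF3 source and type columns (recycled); existing
#'   `source`/`type` columns on `x` take precedence.
#' @export
write_gff3 <- function(x, path, source = "rdnafoot", type = "region") {
  src <- if (!is.null(x$source)) x$source else rep_len(source, nrow(x))
  typ <- if (!is.null(x$type)) x$type else rep_len(type, nrow(x))
  attrs <- if (!is.null(x$attributes)) {
    x$attributes
  } else {
    ifelse(is.na(x$label), ".", paste0("ID=", x$label))
  }
  score <- ifelse(is.na(x$score), ".", formatC(x$score, format = "f", digits = 6))
  lines <- paste(x$seqnames, src, typ, x$start + 1L, x$end, score,
                 x$strand, ".", attrs, sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' @rdname write_bed
#' @export
write_bedgraph <- function(x, path) {
  score <- formatC(ifelse(is.na(x$score), 0, x$score), format = "f", digits = 6)
  writeLines(paste(x$seqnames, x$start, x$end, score, sep = "\t"), path)
  invisible(path)
}
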