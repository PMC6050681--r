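# Readers and writers for the three on-disk track dialects. The readers
# enforce the package's coordinate contracts (half-open, non-empty,
# within-chromosome) and report the offending line number on failure;
# name/score/strand are kept as verbatim strings so rows round-trip
# byte-identically through the writers.

read_track_lines <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  list(lines = lines[keep], numbers = which(keep))
}

split_fields <- function(line) strsplit(trimws(line), "[ \t]+")[[1]]

parse_coord <- function(x, path, lineno, what) {
  v <- suppressWarnings(as.numeric(x))
  if (is.na(v) || v != floor(v) || v < 0) {
    stop(sprintf("%s:%d: malformed %s coordinate '%s'", path, lineno, what, x))
  }
  v
}

check_interval_fields <- function(chrom, start, end, path, lineno, chroms) {
  if (end <= start) {
    stop(sprintf("%s:%d: end (%s) must exceed start (%s); zero-length rows are rejected",
                 path, lineno, end, start))
  }
  if (!is.null(chroms)) {
    if (!(chrom %in% chroms$name)) {
      stop(sprintf("%s:%d: unknown chromosome '%s'", path, lineno, chrom))
    }
    if (end > chrom_length(chroms, chrom)) {
      stop(sprintf("%s:%d: interval end %s exceeds %s length %s",
                   path, lineno, end, chrom, chrom_length(chroms, chrom)))
    }
  }
}

bed_identity <- function(df) {
  paste(df$chrom, df$start, df$end, df$name, df$score, df$strand, df$rest,
        sep = "\x1f")
}

sort_bed <- function(df) {
  df[order(df$chrom, df$start, df$end, df$name), , drop = FALSE]
}

#' Read a BED file
#'
#' Accepts 3 or more tab- or space-separated columns; `track`, `browser`
#' and `#` comment lines are skipped. Records are validated (integral
#' coordinates, `end > start`, known chromosome when `chroms` is given)
#' with errors naming the offending line, and returned sorted by
#' `(chrom, start, end, name)`. Columns beyond the sixth are kept
#' verbatim in `rest`.
#'
#' @param path BED file path.
#' @param chroms Optional [chrom_info()] used to validate coordinates.
#' @return A data.frame with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`, `rest`, `ncols`, `id` (identity string used for
#'   deduplication). Missing optional fields are empty strings.
#' @export
read_bed <- function(path, chroms = NULL) {
  src <- read_track_lines(path)
  rows <- vector("list", length(src$lines))
  for (i in seq_along(src$lines)) {
    f <- split_fields(src$lines[i])
    lineno <- src$numbers[i]
    if (length(f) < 3L) {
      stop(sprintf("%s:%d: BED needs at least 3 columns", path, lineno))
    }
    start <- parse_coord(f[2], path, lineno, "start")
    end <- parse_coord(f[3], path, lineno, "end")
    check_interval_fields(f[1], start, end, path, lineno, chroms)
    strand <- if (length(f) >= 6L) f[6] else ""
    if (!strand %in% c("", "+", "-", ".")) {
      stop(sprintf("%s:%d: bad strand '%s'", path, lineno, strand))
    }
    rows[[i]] <- data.frame(
      chrom = f[1], start = start, end = end,
      name = if (length(f) >= 4L) f[4] else "",
      score = if (length(f) >= 5L) f[5] else "",
      strand = strand,
      rest = if (length(f) > 6L) paste(f[-(1:6)], collapse = "\t") else "",
      ncols = length(f),
      stringsAsFactors = FALSE)
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               name = character(0), score = character(0), strand = character(0),
               rest = character(0), ncols = integer(0), stringsAsFactors = FALSE)
  df <- sort_bed(df)
  df$id <- bed_identity(df)
  rownames(df) <- NULL
  df
}

#' Write BED records
#'
#' Each record is written with as many columns as it was read with, so
#' the first six columns round-trip byte-identically.
#'
#' @param df A record table from [read_bed()].
#' @param path Output path.
#' @export
write_bed <- function(df, path) {
  lines <- vapply(seq_len(nrow(df)), function(i) {
    f <- c(df$chrom[i], format(df$start[i], scientific = FALSE),
           format(df$end[i], scientific = FALSE),
           df$name[i], df$score[i], df$strand[i])
    n <- min(df$ncols[i], 6L)
    out <- paste(f[seq_len(n)], collapse = "\t")
    if (df$ncols[i] > 6L) out <- paste(out, df$rest[i], sep = "\t")
    out
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a bedGraph file
#'
#' Four columns: chrom, start, end, value — a piecewise-constant signal.
#' Segments on a chromosome must not overlap; gaps between segments mean
#' "no data" and are excluded from base counts. Segments are returned
#' sorted by position.
#'
#' @param path bedGraph file path.
#' @param chroms Optional [chrom_info()] for coordinate validation.
#' @return A data.frame with columns `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path, chroms = NULL) {
  src <- read_track_lines(path)
  rows <- vector("list", length(src$lines))
  for (i in seq_along(src$lines)) {
    f <- split_fields(src$lines[i])
    lineno <- src$numbers[i]
    if (length(f) != 4L) {
      stop(sprintf("%s:%d: bedGraph needs exactly 4 columns", path, lineno))
    }
    start <- parse_coord(f[2], path, lineno, "start")
    end <- parse_coord(f[3], path, lineno, "end")
    check_interval_fields(f[1], start, end, path, lineno, chroms)
    value <- suppressWarnings(as.numeric(f[4]))
    if (is.na(value) || !is.finite(value)) {
      stop(sprintf("%s:%d: malformed value '%s'", path, lineno, f[4]))
    }
    rows[[i]] <- data.frame(chrom = f[1], start = start, end = end,
                            value = value, stringsAsFactors = FALSE)
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               value = numeric(0), stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  for (ch in unique(df$chrom)) {
    seg <- df[df$chrom == ch, ]
    if (nrow(seg) > 1L && any(seg$start[-1] < seg$end[-nrow(seg)])) {
      bad <- which(seg$start[-1] < seg$end[-nrow(seg)])[1]
      stop(sprintf("%s: overlapping segments on %s near %s-%s",
                   path, ch, seg$start[bad + 1], seg$end[bad]))
    }
  }
  rownames(df) <- NULL
  df
}

#' Write a bedGraph file
#' @param df Segment table as from [read_bedgraph()].
#' @param path Output path.
#' @export
write_bedgraph <- function(df, path) {
  lines <- sprintf("%s\t%s\t%s\t%s", df$chrom,
                   format(df$start, scientific = FALSE),
                   format(df$end, scientific = FALSE),
                   format(df$value, digits = 15, scientific = FALSE))
  writeLines(lines, path)
  invisible(path)
}

#' Read a paired-interval interaction file
#'
#' BEDPE-style: chrom1 start1 end1 chrom2 start2 end2 intensity. Both
#' anchors are validated as half-open intervals; intensity must be a
#' finite non-negative number.
#'
#' @param path Interaction file path.
#' @param chroms Optional [chrom_info()] for validation.
#' @return A data.frame with both anchors, `intensity` and an `id`
#'   identity column.
#' @export
read_interactions <- function(path, chroms = NULL) {
  src <- read_track_lines(path)
  rows <- vector("list", length(src$lines))
  for (i in seq_along(src$lines)) {
    f <- split_fields(src$lines[i])
    lineno <- src$numbers[i]
    if (length(f) < 7L) {
      stop(sprintf("%s:%d: interaction rows need 7 columns", path, lineno))
    }
    s1 <- parse_coord(f[2], path, lineno, "start1")
    e1 <- parse_coord(f[3], path, lineno, "end1")
    s2 <- parse_coord(f[5], path, lineno, "start2")
    e2 <- parse_coord(f[6], path, lineno, "end2")
    check_interval_fields(f[1], s1, e1, path, lineno, chroms)
    check_interval_fields(f[4], s2, e2, path, lineno, chroms)
    intensity <- suppressWarnings(as.numeric(f[7]))
    if (is.na(intensity) || !is.finite(intensity) || intensity < 0) {
      stop(sprintf("%s:%d: intensity must be a finite non-negative number, got '%s'",
                   path, lineno, f[7]))
    }
    rows[[i]] <- data.frame(chrom1 = f[1], start1 = s1, end1 = e1,
                            chrom2 = f[4], start2 = s2, end2 = e2,
                            intensity = intensity, stringsAsFactors = FALSE)
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom1 = character(0), start1 = numeric(0), end1 = numeric(0),
               chrom2 = character(0), start2 = numeric(0), end2 = numeric(0),
               intensity = numeric(0), stringsAsFactors = FALSE)
  df <- df[order(df$chrom1, df$start1, df$end1, df$chrom2, df$start2, df$end2), ,
           drop = FALSE]
  df$id <- paste(df$chrom1, df$start1, df$end1, df$chrom2, df$start2, df$end2,
                 df$intensity, sep = "\x1f")
  rownames(df) <- NULL
  df
}

#' Write an interaction file
#' @param df Table as from [read_interactions()].
#' @param path Output path.
#' @export
write_interactions <- function(df, path) {
  lines <- sprintf("%s\t%s\t%s\t%s\t%s\t%s\t%s",
                   df$chrom1, format(df$start1, scientific = FALSE),
                   format(df$end1, scientific = FALSE),
                   df$chrom2, format(df$start2, scientific = FALSE),
                   format(df$end2, scientific = FALSE),
                   format(df$intensity, digits = 15, scientific = FALSE))
  writeLines(lines, path)
  invisible(path)
}
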