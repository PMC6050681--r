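#' Genomic interval
#'
#' Construct a validated genomic interval. Coordinates are 0-based,
#' half-open throughout the package (the BED convention): `start` is the
#' first base included, `end` the first base excluded. Zero-length
#' intervals are rejected.
#'
#' @param chrom Chromosome name.
#' @param start 0-based inclusive start (>= 0).
#' @param end 0-based exclusive end (> start).
#' @param chrom_info Optional [chrom_info()] table; when supplied the
#'   interval must lie within the named chromosome.
#' @return A list of class `genomic_interval` with fields `chrom`,
#'   `start`, `end`.
#' @export
#' @examples
#' genomic_interval("chr1", 0, 100)
genomic_interval <- function(chrom, start, end, chrom_info = NULL) {
  stopifnot(is.character(chrom), length(chrom) == 1L)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (is.na(start) || is.na(end)) {
    stop("interval coordinates must be numbers")
  }
  if (start < 0) {
    stop(sprintf("interval start must be >= 0, got %s", start))
  }
  if (end <= start) {
    stop(sprintf("interval end must exceed start (zero-length rejected): [%s, %s)",
                 start, end))
  }
  if (!is.null(chrom_info)) {
    len <- chrom_length(chrom_info, chrom)
    if (end > len) {
      stop(sprintf("interval [%s, %s) exceeds length %s of %s",
                   start, end, len, chrom))
    }
  }
  structure(list(chrom = chrom, start = start, end = end),
            class = "genomic_interval")
}

#' @export
format.genomic_interval <- function(x, ...) {
  sprintf("%s:%s-%s", x$chrom, format(x$start, scientific = FALSE),
          format(x$end, scientific = FALSE))
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat("<genomic_interval>", format(x), "\n")
  invisible(x)
}

interval_width <- function(i) i$end - i$start

#' Chromosome size table
#'
#' @param names Chromosome names (unique).
#' @param lengths Positive integer lengths in bases.
#' @return A data.frame of class `chrom_info` with columns `name`, `length`.
#' @export
chrom_info <- function(names, lengths) {
  lengths <- as.numeric(lengths)
  if (anyDuplicated(names)) stop("chromosome names must be unique")
  if (any(is.na(lengths)) || any(lengths <= 0)) {
    stop("chromosome lengths must be positive")
  }
  structure(data.frame(name = as.character(names), length = lengths,
                       stringsAsFactors = FALSE),
            class = c("chrom_info", "data.frame"))
}

#' Read a UCSC-style chrom.sizes file
#'
#' Two whitespace-separated columns: chromosome name and length.
#'
#' @param path File path.
#' @return A [chrom_info()] table.
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, header = FALSE, col.names = c("name", "length"),
                           colClasses = c("character", "numeric"),
                           comment.char = "#")
  chrom_info(tab$name, tab$length)
}

chrom_length <- function(info, chrom) {
  i <- match(chrom, info$name)
  if (is.na(i)) stop(sprintf("unknown chromosome: %s", chrom))
  info$length[i]
}

#' Do two intervals overlap?
#'
#' Half-open semantics: intervals sharing only a boundary do not overlap.
#'
#' @param a,b `genomic_interval` objects.
#' @return `TRUE` iff same chromosome and the open spans intersect.
#' @export
overlaps <- function(a, b) {
  a$chrom == b$chrom && a$start < b$end && b$start < a$end
}

# --- interval-set helpers (half-open, numeric) ------------------------------
# Sets are data.frames with columns start, end, kept sorted and disjoint
# (touching intervals are coalesced). Plain sweep-line arithmetic; the
# independent cross-check against IRanges lives in the test suite.

empty_iset <- function() data.frame(start = numeric(0), end = numeric(0))

iset <- function(start, end) {
  stopifnot(length(start) == length(end))
  iset_normalize(data.frame(start = start, end = end))
}

iset_normalize <- function(s) {
  s <- s[s$end > s$start, , drop = FALSE]
  if (nrow(s) <= 1L) { rownames(s) <- NULL; return(s) }
  s <- s[order(s$start, s$end), , drop = FALSE]
  out_s <- numeric(nrow(s)); out_e <- numeric(nrow(s))
  k <- 1L; out_s[1] <- s$start[1]; out_e[1] <- s$end[1]
  for (i in 2:nrow(s)) {
    if (s$start[i] <= out_e[k]) {
      out_e[k] <- max(out_e[k], s$end[i])
    } else {
      k <- k + 1L; out_s[k] <- s$start[i]; out_e[k] <- s$end[i]
    }
  }
  data.frame(start = out_s[seq_len(k)], end = out_e[seq_len(k)])
}

iset_union <- function(a, b) iset_normalize(rbind(a, b))

iset_diff <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(a)
  rows_s <- numeric(0); rows_e <- numeric(0)
  for (i in seq_len(nrow(a))) {
    cur_s <- a$start[i]; cur_e <- a$end[i]
    hit <- which(b$start < cur_e & cur_s < b$end)
    for (j in hit) {
      if (b$start[j] > cur_s) {
        rows_s <- c(rows_s, cur_s); rows_e <- c(rows_e, b$start[j])
      }
      cur_s <- max(cur_s, b$end[j])
      if (cur_s >= cur_e) break
    }
    if (cur_s < cur_e) {
      rows_s <- c(rows_s, cur_s); rows_e <- c(rows_e, cur_e)
    }
  }
  data.frame(start = rows_s, end = rows_e)
}

iset_intersect <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(empty_iset())
  rows_s <- numeric(0); rows_e <- numeric(0)
  for (i in seq_len(nrow(a))) {
    hit <- which(b$start < a$end[i] & a$start[i] < b$end)
    for (j in hit) {
      rows_s <- c(rows_s, max(a$start[i], b$start[j]))
      rows_e <- c(rows_e, min(a$end[i], b$end[j]))
    }
  }
  iset_normalize(data.frame(start = rows_s, end = rows_e))
}

iset_covers <- function(s, start, end) {
  # TRUE iff [start, end) is fully inside the set
  nrow(iset_diff(data.frame(start = start, end = end), s)) == 0L
}

iset_total <- function(s) sum(s$end - s$start)

#' Subtract cached coverage from a query region
#'
#' Returns the minimal ordered set of disjoint sub-intervals of `query`
#' that are not covered by `covered` — the spans that still have to be
#' fetched from the backend.
#'
#' @param query A `genomic_interval`.
#' @param covered A list of disjoint, sorted `genomic_interval`s on the
#'   same chromosome as `query`.
#' @return A list of `genomic_interval`s (possibly empty).
#' @export
#' @examples
#' q <- genomic_interval("chr1", 50, 150)
#' cov <- list(genomic_interval("chr1", 0, 100))
#' subtract_covered(q, cov)  # chr1:100-150
subtract_covered <- function(query, covered) {
  if (length(covered) > 0L) {
    chroms <- vapply(covered, function(x) x$chrom, character(1))
    if (any(chroms != query$chrom)) {
      stop("covered intervals must be on the query chromosome")
    }
  }
  cov <- if (length(covered)) {
    data.frame(start = vapply(covered, function(x) x$start, numeric(1)),
               end = vapply(covered, function(x) x$end, numeric(1)))
  } else {
    empty_iset()
  }
  res <- iset_diff(data.frame(start = query$start, end = query$end), cov)
  lapply(seq_len(nrow(res)), function(i) {
    genomic_interval(query$chrom, res$start[i], res$end[i])
  })
}

#' Clamp an interval to its chromosome
#'
#' @param i A `genomic_interval`.
#' @param info A [chrom_info()] table containing `i$chrom`.
#' @return The intersection of `i` with `[0, length)`; error if empty.
#' @export
clamp_to_chromosome <- function(i, info) {
  len <- chrom_length(info, i$chrom)
  s <- max(0, i$start)
  e <- min(len, i$end)
  if (e <= s) {
    stop(sprintf("interval %s lies outside chromosome of length %s",
                 format(i), len))
  }
  genomic_interval(i$chrom, s, e)
}

#' Viewport: a query region plus its drawing width in pixels
#'
#' The resolution (bases per pixel) of a viewport is
#' `width(region) / pixel_width`; it drives the depth of the Pine cache.
#'
#' @param chrom,start,end Query region (0-based half-open).
#' @param pixel_width Horizontal pixels of the drawing area (>= 1).
#' @return A list of class `viewport` with fields `region`, `pixel_width`.
#' @export
viewport <- function(chrom, start, end, pixel_width) {
  pixel_width <- as.integer(pixel_width)
  if (is.na(pixel_width) || pixel_width < 1L) {
    stop("pixel_width must be a positive integer")
  }
  structure(list(region = genomic_interval(chrom, start, end),
                 pixel_width = pixel_width),
            class = "viewport")
}

view_resolution <- function(view) {
  interval_width(view$region) / view$pixel_width
}
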