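# Brute-force oracles and tiny in-code fixtures shared by the tests.
# The oracles are deliberately naive (per-base membership, linear scans)
# and independent of the package's tree/interval machinery.

gi <- function(chrom, start, end) genomic_interval(chrom, start, end)

toy_chroms <- function(...) {
  v <- c(...)
  chrom_info(names(v), unname(v))
}

# per-base set difference: which bases of [qs,qe) are not covered
bf_uncovered_bases <- function(qs, qe, covered) {
  bases <- qs:(qe - 1)
  inside <- rep(FALSE, length(bases))
  for (iv in covered) {
    inside <- inside | (bases >= iv$start & bases < iv$end)
  }
  bases[!inside]
}

# turn a sorted base vector into intervals
bf_bases_to_intervals <- function(bases) {
  if (length(bases) == 0L) return(list())
  brk <- c(0L, which(diff(bases) > 1L), length(bases))
  lapply(seq_len(length(brk) - 1L), function(i) {
    c(bases[brk[i] + 1L], bases[brk[i + 1L]] + 1L)
  })
}

# naive overlap scan over a BED-style data.frame
bf_overlapping <- function(df, chrom, start, end) {
  hit <- df$chrom == chrom & df$start < end & start < df$end
  out <- df[hit, , drop = FALSE]
  out[order(out$start, out$end, out$name), , drop = FALSE]
}

# per-base signal vector from bedGraph segments (NA in gaps)
bf_signal_vector <- function(segments, chrom, chrom_len) {
  v <- rep(NA_real_, chrom_len)
  seg <- segments[segments$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(seg))) {
    v[(seg$start[i] + 1):seg$end[i]] <- seg$value[i]
  }
  v
}

# base-by-base summary over [start, end) of a per-base vector
bf_summary <- function(vec, start, end) {
  vals <- vec[(start + 1):end]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) return(summary_empty())
  summary_stats(length(vals), sum(vals), sum(vals^2), max(vals), min(vals))
}

# build a BED record table in code
make_bed <- function(chrom, start, end, name = sprintf("r%03d", seq_along(start))) {
  path <- withr::local_tempfile(fileext = ".bed",
                                .local_envir = parent.frame())
  writeLines(sprintf("%s\t%d\t%d\t%s", chrom, start, end, name), path)
  path
}

read_toy_bed <- function(chrom, start, end,
                         name = sprintf("r%03d", seq_along(start)),
                         chroms = NULL) {
  read_bed(make_bed(chrom, start, end, name), chroms)
}

# per-base bedGraph (value v_i on base i) for toy signals
make_base_bedgraph <- function(chrom, values, offset = 0) {
  path <- withr::local_tempfile(fileext = ".bedgraph",
                                .local_envir = parent.frame())
  idx <- seq_along(values) - 1 + offset
  writeLines(sprintf("%s\t%d\t%d\t%s", chrom, idx, idx + 1, values), path)
  path
}

# exact-arithmetic oracle for the depth formula: the smallest depth d
# with n^d * view_length >= chrom_length * pixel_width (up to the same
# documented epsilon), i.e. ceiling(log_n(chrom_length / resolution))
# without floating logarithms.
bf_depth <- function(L, view, px, n = 20, min_depth = 1, eps = 1e-9) {
  L <- as.numeric(L); view <- as.numeric(view); px <- as.numeric(px)
  d <- 0
  while (n^d * view < L * px * (1 - eps)) d <- d + 1
  max(min_depth, d)
}

make_backend <- function(chroms, bed = NULL, bedgraph = NULL, bedpe = NULL) {
  be <- data_backend(chroms)
  if (!is.null(bed)) backend_add_track(be, "sparse", "sparse", bed)
  if (!is.null(bedgraph)) backend_add_track(be, "dense", "dense", bedgraph)
  if (!is.null(bedpe)) backend_add_track(be, "interaction", "interaction", bedpe)
  be
}
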