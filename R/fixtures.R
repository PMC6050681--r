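# Seeded synthetic track generation. Random streams are namespaced per
# track kind (sub-seeds derived once from the master seed), so adding a
# track kind never perturbs the fixtures of another — golden files stay
# stable.

#' Specification of a synthetic track set
#'
#' Defaults emulate a compact browsing scenario: three ~5 kb
#' chromosomes, ~500 peak-like sparse records with geometric lengths,
#' ~200 disjoint piecewise-constant signal segments with log-normal
#' values separated by gaps, and ~100 paired-interval interactions
#' (mostly intra-chromosomal) with log-normal intensities.
#'
#' @param seed Master seed; the same spec and seed give byte-identical
#'   files.
#' @param chroms Named numeric vector of chromosome lengths.
#' @param sparse_n Number of sparse records.
#' @param sparse_mean_len Mean record length (geometric).
#' @param dense_segments Number of dense signal segments.
#' @param dense_meanlog,dense_sdlog Log-normal value parameters.
#' @param interaction_n Number of interaction pairs.
#' @param intra_prob Probability that both anchors share a chromosome.
#' @param anchor_len Range of anchor lengths (uniform).
#' @param intensity_meanlog,intensity_sdlog Log-normal intensity
#'   parameters.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L,
                         chroms = c(chrI = 5000, chrII = 5000, chrIII = 5000),
                         sparse_n = 500L, sparse_mean_len = 80,
                         dense_segments = 200L, dense_meanlog = 0,
                         dense_sdlog = 1, interaction_n = 100L,
                         intra_prob = 0.7, anchor_len = c(20, 60),
                         intensity_meanlog = 0, intensity_sdlog = 1) {
  structure(as.list(environment()), class = "fixture_spec")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}

sub_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Generate synthetic track files
#'
#' Writes `chrom.sizes`, `sparse.bed`, `dense.bedgraph` and
#' `interactions.bedpe` under `out_dir` and returns a manifest of
#' paths and md5 checksums. Deterministic given the spec.
#'
#' @param spec A [fixture_spec()].
#' @param out_dir Output directory (created if needed).
#' @return Data.frame manifest with columns `file`, `md5`.
#' @export
gen_tracks <- function(spec, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- sub_seeds(spec$seed, 3L)
  chroms <- chrom_info(names(spec$chroms), unname(spec$chroms))

  sizes_path <- file.path(out_dir, "chrom.sizes")
  writeLines(sprintf("%s\t%s", chroms$name,
                     format(chroms$length, scientific = FALSE)), sizes_path)

  bed_path <- file.path(out_dir, "sparse.bed")
  bed <- with_seed(seeds[1], gen_sparse(spec, chroms))
  write_bed(bed, bed_path)

  bg_path <- file.path(out_dir, "dense.bedgraph")
  bg <- with_seed(seeds[2], gen_dense(spec, chroms))
  write_bedgraph(bg, bg_path)

  bedpe_path <- file.path(out_dir, "interactions.bedpe")
  bedpe <- with_seed(seeds[3], gen_interactions(spec, chroms))
  write_interactions(bedpe, bedpe_path)

  files <- c(sizes_path, bed_path, bg_path, bedpe_path)
  data.frame(file = files, md5 = unname(tools::md5sum(files)),
             stringsAsFactors = FALSE)
}

gen_sparse <- function(spec, chroms) {
  n <- spec$sparse_n
  if (n == 0L) {
    df <- empty_bed_table()
    return(df)
  }
  ci <- sample(nrow(chroms), n, replace = TRUE, prob = chroms$length)
  len <- pmin(stats::rgeom(n, 1 / spec$sparse_mean_len) + 1,
              chroms$length[ci] - 1)
  start <- floor(stats::runif(n, 0, chroms$length[ci] - len))
  df <- data.frame(chrom = chroms$name[ci], start = start, end = start + len,
                   name = sprintf("feat%04d", seq_len(n)),
                   score = as.character(sample.int(1000L, n, replace = TRUE)),
                   strand = sample(c("+", "-", "."), n, replace = TRUE),
                   rest = "", ncols = 6L, stringsAsFactors = FALSE)
  df <- sort_bed(df)
  df$id <- bed_identity(df)
  rownames(df) <- NULL
  df
}

gen_dense <- function(spec, chroms) {
  total <- sum(chroms$length)
  per <- pmax(1L, round(spec$dense_segments * chroms$length / total))
  rows <- list()
  for (i in seq_len(nrow(chroms))) {
    k <- per[i]
    # 2k sorted breakpoints; every other interval is a data segment,
    # the rest are gaps, so segments are disjoint by construction
    breaks <- sort(sample.int(chroms$length[i] - 1L, 2L * k))
    a <- breaks[seq(1, 2 * k, by = 2)]
    b <- breaks[seq(2, 2 * k, by = 2)]
    keep <- b > a
    rows[[i]] <- data.frame(chrom = chroms$name[i], start = a[keep],
                            end = b[keep],
                            value = round(stats::rlnorm(sum(keep),
                                                        spec$dense_meanlog,
                                                        spec$dense_sdlog), 4),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out[order(out$chrom, out$start), , drop = FALSE]
}

gen_interactions <- function(spec, chroms) {
  n <- spec$interaction_n
  if (n == 0L) {
    return(read_interactions_text(character(0)))
  }
  draw_anchor <- function(ci) {
    len <- floor(stats::runif(length(ci), spec$anchor_len[1],
                              spec$anchor_len[2] + 1))
    start <- floor(stats::runif(length(ci), 0, chroms$length[ci] - len))
    data.frame(chrom = chroms$name[ci], start = start, end = start + len)
  }
  c1 <- sample(nrow(chroms), n, replace = TRUE)
  intra <- stats::runif(n) < spec$intra_prob
  c2 <- ifelse(intra, c1, sample(nrow(chroms), n, replace = TRUE))
  a1 <- draw_anchor(c1)
  a2 <- draw_anchor(c2)
  df <- data.frame(chrom1 = a1$chrom, start1 = a1$start, end1 = a1$end,
                   chrom2 = a2$chrom, start2 = a2$start, end2 = a2$end,
                   intensity = round(stats::rlnorm(n, spec$intensity_meanlog,
                                                   spec$intensity_sdlog), 4),
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom1, df$start1, df$end1, df$chrom2, df$start2,
                 df$end2), , drop = FALSE]
  df$id <- paste(df$chrom1, df$start1, df$end1, df$chrom2, df$start2, df$end2,
                 df$intensity, sep = "\x1f")
  rownames(df) <- NULL
  df
}

#' Generate a random browsing trace
#'
#' A seeded random walk of view changes: shifts by half a view, zooms
#' in/out by the branching factor, and occasional jumps to a random
#' chromosome. Interaction steps get an independent second viewport.
#'
#' @param seed Seed for the walk.
#' @param chroms A [chrom_info()] table.
#' @param tracks Character vector of track ids to query (all per step).
#' @param n_steps Number of queries.
#' @param pixel_width Viewport pixel width.
#' @param interaction_tracks Subset of `tracks` that are interaction
#'   tracks (these steps carry a `second_view`).
#' @return A list of trace steps, each a list with `tracks`, `chrom`,
#'   `start`, `end`, `pixels` and optionally `second_view`.
#' @export
gen_trace <- function(seed, chroms, tracks, n_steps = 200L, pixel_width = 100L,
                      interaction_tracks = character(0)) {
  with_seed(seed, {
    steps <- vector("list", n_steps)
    ci <- sample(nrow(chroms), 1)
    L <- chroms$length[ci]
    w <- max(64, floor(L / 8))
    s <- floor(stats::runif(1, 0, L - w))
    for (i in seq_len(n_steps)) {
      action <- sample(c("shift", "zoom_in", "zoom_out", "jump"), 1,
                       prob = c(0.45, 0.2, 0.2, 0.15))
      if (action == "jump") {
        ci <- sample(nrow(chroms), 1)
        L <- chroms$length[ci]
        w <- max(64, floor(L / 8))
        s <- floor(stats::runif(1, 0, L - w))
      } else if (action == "shift") {
        s <- s + sample(c(-1, 1), 1) * floor(w / 2)
      } else if (action == "zoom_in") {
        s <- s + floor(w / 4); w <- max(32, floor(w / 4))
      } else {
        s <- s - floor(w / 2); w <- min(L, w * 4)
      }
      s <- max(0, min(s, L - w))
      step <- list(tracks = tracks, chrom = chroms$name[ci], start = s,
                   end = s + w, pixels = pixel_width)
      if (length(interaction_tracks) > 0L) {
        cj <- sample(nrow(chroms), 1)
        L2 <- chroms$length[cj]
        w2 <- min(L2, w * sample(c(1, 4, 16), 1))
        s2 <- floor(stats::runif(1, 0, L2 - w2 + 1))
        step$second_view <- list(chrom = chroms$name[cj], start = s2,
                                 end = s2 + w2, pixels = pixel_width)
      }
      steps[[i]] <- step
    }
    steps
  })
}

#' Write a trace as JSON lines
#' @param steps A list of trace steps ([gen_trace()]).
#' @param path Output path.
#' @export
write_trace <- function(steps, path) {
  lines <- vapply(steps, function(s) {
    jsonlite::toJSON(c(list(action = "query"), s), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a JSON-lines trace file
#' @param path Trace path.
#' @return A list of trace steps.
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(l) {
    s <- jsonlite::fromJSON(l, simplifyVector = TRUE)
    s$action <- NULL
    s
  })
}

step_view <- function(step) {
  viewport(step$chrom, step$start, step$end, step$pixels)
}

step_second_view <- function(step) {
  sv <- step$second_view
  if (is.null(sv)) return(NULL)
  viewport(sv$chrom, sv$start, sv$end, sv$pixels)
}

#' Run a trace against a session
#'
#' @param ses A [cache_session()].
#' @param steps Trace steps ([gen_trace()] or [read_trace()]).
#' @return A list of `display_payload`s, one per step.
#' @export
run_trace <- function(ses, steps) {
  lapply(steps, function(step) {
    session_query(ses, unlist(step$tracks), step_view(step),
                  step_second_view(step))
  })
}
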