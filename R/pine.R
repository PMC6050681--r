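# Pine: a fixed-branching multiscale cache of dense-signal summaries
# for one chromosome. The root spans the chromosome; nodes overlapping
# the query region are partitioned into n children (n = 20 by default)
# until the depth demanded by the viewing resolution is reached.
# Summaries (bases, sum, sum of squares, max, min) are fetched for the
# target-depth nodes and aggregated bottom-up; later queries extend the
# structure and fetch only spans never summarized before. Nodes are
# environments so the tree mutates in place, like the browser cache it
# models.

#' Pine configuration
#'
#' @param branching_n Children per partition (>= 2). Default 20.
#' @param min_depth Smallest data depth; the root alone is never the
#'   data level. Default 1.
#' @param epsilon Tolerance inside the ceiling of the depth formula so
#'   chromosome lengths that are exact powers of `branching_n` do not
#'   round up a level. Default 1e-9.
#' @return A list of class `pine_config`.
#' @export
pine_config <- function(branching_n = 20L, min_depth = 1L, epsilon = 1e-9) {
  branching_n <- as.integer(branching_n)
  if (branching_n < 2L) stop("branching_n must be >= 2")
  structure(list(branching_n = branching_n, min_depth = as.integer(min_depth),
                 epsilon = epsilon),
            class = "pine_config")
}

#' Depth of the Pine tree for a view
#'
#' The viewing resolution is `r = view_length / pixel_width` bases per
#' pixel; the tree is built to depth
#' `ceiling(log_n(chrom_length) - log_n(r))`, evaluated as
#' `ceiling(log_n(chrom_length / r) - epsilon)` and floored at
#' `min_depth`.
#'
#' @param chrom_length Chromosome length in bases.
#' @param view_length Length of the viewed region in bases.
#' @param pixel_width Horizontal pixels of the drawing area.
#' @param config A [pine_config()].
#' @return Integer depth.
#' @export
#' @examples
#' pine_depth(8000, 400, 400)  # resolution 1 bp/px, 8000 = 20^3 -> depth 3
pine_depth <- function(chrom_length, view_length, pixel_width,
                       config = pine_config()) {
  stopifnot(chrom_length > 0, view_length > 0, pixel_width > 0)
  r <- view_length / pixel_width
  d <- ceiling(log(chrom_length / r, base = config$branching_n) - config$epsilon)
  max(config$min_depth, as.integer(d))
}

# Equal partition with indivisible remainders: child k spans
# [left + floor(k*len/n), left + floor((k+1)*len/n)); zero-width child
# slots (len < n) are not materialized, so the children always tile the
# parent span exactly.
partition_span <- function(left, right, n) {
  len <- right - left
  bounds <- unique(left + floor((0:n) * len / n))
  data.frame(left = bounds[-length(bounds)], right = bounds[-1])
}

pine_node <- function(left, right, depth, placeholder, life = 10L) {
  nd <- new.env(parent = emptyenv())
  nd$left <- left; nd$right <- right; nd$depth <- depth
  nd$placeholder <- placeholder
  nd$children <- NULL
  nd$summary <- NULL
  nd$direct <- FALSE
  nd$life <- as.integer(life)
  nd$right_sib <- NULL
  nd
}

node_overlaps <- function(nd, region) {
  nd$left < region$end && region$start < nd$right
}

#' Build a Pine structure for a first query (no data loaded)
#'
#' Creates the root over the whole chromosome and partitions every
#' query-overlapping node into `branching_n` children down to the depth
#' [pine_depth()] computes for the viewport. Children not overlapping
#' the query are placeholders. No summaries are loaded.
#'
#' @param chroms A [chrom_info()] table.
#' @param view A [viewport()]; its region must lie inside the
#'   chromosome.
#' @param config A [pine_config()].
#' @return An environment of class `pine_tree`.
#' @export
pine_build <- function(chroms, view, config = pine_config()) {
  region <- clamp_to_chromosome(view$region, chroms)
  L <- chrom_length(chroms, region$chrom)
  tree <- new.env(parent = emptyenv())
  class(tree) <- "pine_tree"
  tree$chrom <- region$chrom
  tree$chrom_len <- L
  tree$config <- config
  tree$root <- pine_node(0, L, 0L, FALSE)
  tree$depth <- pine_depth(L, interval_width(region), view$pixel_width, config)
  pine_expand(tree, region, tree$depth)
  pine_relink(tree)
  tree
}

# Partition query-overlapping lineages down to `depth`. Placeholder
# nodes that overlap the query are revived (they become structural
# nodes and get children); children that do not overlap stay
# placeholders. Nodes at `depth` itself are never partitioned here.
pine_expand <- function(tree, region, depth) {
  walk <- function(nd) {
    if (nd$depth >= depth) return(invisible(NULL))
    if (!node_overlaps(nd, region)) return(invisible(NULL))
    if (nd$placeholder) {
      nd$placeholder <- FALSE
      nd$life <- 10L
    }
    if (is.null(nd$children)) {
      parts <- partition_span(nd$left, nd$right, tree$config$branching_n)
      nd$children <- lapply(seq_len(nrow(parts)), function(i) {
        child_region <- list(start = parts$left[i], end = parts$right[i])
        ph <- !(parts$left[i] < region$end && region$start < parts$right[i])
        pine_node(parts$left[i], parts$right[i], nd$depth + 1L, ph)
      })
    }
    for (ch in nd$children) walk(ch)
    invisible(NULL)
  }
  walk(tree$root)
  invisible(tree)
}

# Link every node to its right-hand neighbour at the same depth.
pine_relink <- function(tree) {
  level <- list(tree$root)
  while (length(level) > 0L) {
    for (i in seq_along(level)) {
      level[[i]]$right_sib <- if (i < length(level)) level[[i + 1L]] else NULL
    }
    nxt <- list()
    for (nd in level) {
      if (!is.null(nd$children)) nxt <- c(nxt, nd$children)
    }
    level <- nxt
  }
  invisible(tree)
}

pine_nodes_at_depth <- function(tree, depth, region = NULL) {
  out <- list()
  walk <- function(nd) {
    if (!is.null(region) && !node_overlaps(nd, region)) return(invisible(NULL))
    if (nd$depth == depth) {
      out[[length(out) + 1L]] <<- nd
      return(invisible(NULL))
    }
    if (!is.null(nd$children)) for (ch in nd$children) walk(ch)
    invisible(NULL)
  }
  walk(tree$root)
  out
}

# Give `nd` a summary, reusing whatever its subtree already holds:
# a node with children is completed child by child (placeholder
# children — never-loaded or evicted spans — are fetched directly at
# their own level), then merged; a childless node is fetched whole.
# Nothing already summarized is ever re-fetched.
pine_ensure_summary <- function(nd, backend, track_id, chrom) {
  if (!is.null(nd$summary)) return(invisible(NULL))
  if (is.null(nd$children)) {
    nd$summary <- fetch_summary(backend, track_id,
                                genomic_interval(chrom, nd$left, nd$right),
                                level = nd$depth)
    nd$direct <- TRUE
    nd$placeholder <- FALSE
    return(invisible(NULL))
  }
  for (ch in nd$children) pine_ensure_summary(ch, backend, track_id, chrom)
  nd$summary <- summary_merge(lapply(nd$children, `[[`, "summary"))
  invisible(NULL)
}

# Recompute ancestor summaries bottom-up wherever all children carry
# summaries; nodes with partially loaded children keep what they have.
pine_aggregate <- function(tree) {
  walk <- function(nd) {
    if (is.null(nd$children)) return(invisible(NULL))
    for (ch in nd$children) walk(ch)
    sums <- lapply(nd$children, `[[`, "summary")
    if (!any(vapply(sums, is.null, logical(1)))) {
      nd$summary <- summary_merge(sums)
    }
    invisible(NULL)
  }
  walk(tree$root)
  invisible(tree)
}

#' Load summaries for the current structure
#'
#' Every non-placeholder node at the tree's deepest level requests the
#' summary of its span from the backend; parents are then filled
#' bottom-up to the root. Reloading an already-loaded tree issues no
#' new requests.
#'
#' @param tree A `pine_tree`.
#' @param backend A [data_backend()].
#' @param track_id A registered dense track.
#' @return The tree, invisibly.
#' @export
pine_load <- function(tree, backend, track_id) {
  for (nd in pine_nodes_at_depth(tree, tree$depth)) {
    if (!nd$placeholder) pine_ensure_summary(nd, backend, track_id, tree$chrom)
  }
  pine_aggregate(tree)
  invisible(tree)
}

#' Update a Pine for a new viewport
#'
#' Computes the new depth `d2` for the viewport, extends the structure
#' (partitioning query-overlapping placeholder lineages, keeping
#' existing nodes) to `max(old depth, d2)`, fetches summaries only for
#' depth-`d2` nodes in the query that do not have one — reusing deeper
#' summaries where they exist — and re-aggregates ancestors. Only data
#' never transferred before are requested.
#'
#' @param tree A `pine_tree`.
#' @param view A [viewport()] on the tree's chromosome.
#' @param backend A [data_backend()].
#' @param track_id A registered dense track.
#' @return The tree, invisibly.
#' @export
pine_update <- function(tree, view, backend, track_id) {
  region <- view$region
  if (region$chrom != tree$chrom) stop("viewport on the wrong chromosome")
  if (region$end > tree$chrom_len) stop("viewport exceeds chromosome")
  d2 <- pine_depth(tree$chrom_len, interval_width(region), view$pixel_width,
                   tree$config)
  pine_expand(tree, region, d2)
  tree$depth <- max(tree$depth, d2)
  for (nd in pine_nodes_at_depth(tree, d2, region)) {
    pine_ensure_summary(nd, backend, track_id, tree$chrom)
  }
  pine_aggregate(tree)
  pine_relink(tree)
  invisible(tree)
}

#' Per-pixel profile of a loaded view
#'
#' Splits the viewport into `pixel_width` spans and merges the
#' summaries of the depth-appropriate nodes overlapping each span.
#' Pixels whose spans carry no data bases get a gap marker.
#'
#' @param tree A `pine_tree` that has been updated for this view.
#' @param view A [viewport()].
#' @return A data.frame with one row per pixel: `pixel` (0-based),
#'   `start`, `end`, `mean`, `max`, `min`, `gap`.
#' @export
pine_profile <- function(tree, view) {
  region <- view$region
  if (region$chrom != tree$chrom) stop("viewport on the wrong chromosome")
  d <- pine_depth(tree$chrom_len, interval_width(region), view$pixel_width,
                  tree$config)
  if (d > tree$depth) {
    stop("view needs a deeper tree than is loaded; update the Pine first")
  }
  nodes <- pine_nodes_at_depth(tree, d, region)
  for (nd in nodes) {
    if (nd$placeholder || is.null(nd$summary)) {
      stop(sprintf("span [%s,%s) not loaded at depth %d; update the Pine first",
                   format(nd$left, scientific = FALSE),
                   format(nd$right, scientific = FALSE), d))
    }
  }
  profile_from_spans(
    spans = data.frame(left = vapply(nodes, `[[`, numeric(1), "left"),
                       right = vapply(nodes, `[[`, numeric(1), "right")),
    summaries = lapply(nodes, `[[`, "summary"),
    view = view)
}

# Shared pixel assembly: merge the summaries of spans overlapping each
# pixel span. Used by pine_profile and by the brute-force oracle.
profile_from_spans <- function(spans, summaries, view) {
  region <- view$region
  w <- interval_width(region)
  px <- view$pixel_width
  p_start <- region$start + floor((0:(px - 1)) * w / px)
  p_end <- region$start + floor((1:px) * w / px)
  s_left <- spans$left
  s_right <- spans$right
  s_bases <- vapply(summaries, `[[`, numeric(1), "bases")
  s_sum <- vapply(summaries, `[[`, numeric(1), "sum_values")
  s_max <- vapply(summaries, `[[`, numeric(1), "max_value")
  s_min <- vapply(summaries, `[[`, numeric(1), "min_value")
  mean_v <- rep(NA_real_, px); max_v <- rep(NA_real_, px)
  min_v <- rep(NA_real_, px); gap <- rep(TRUE, px)
  for (i in seq_len(px)) {
    if (p_end[i] <= p_start[i]) next
    hit <- which(s_left < p_end[i] & p_start[i] < s_right & s_bases > 0)
    if (length(hit) == 0L) next
    b <- sum(s_bases[hit])
    mean_v[i] <- sum(s_sum[hit]) / b
    max_v[i] <- max(s_max[hit])
    min_v[i] <- min(s_min[hit])
    gap[i] <- FALSE
  }
  data.frame(pixel = 0:(px - 1L), start = p_start, end = p_end,
             mean = mean_v, max = max_v, min = min_v, gap = gap)
}

# Withering tick for one Pine: nodes overlapping a touched region (and
# therefore all their ancestors, whose spans contain them) reset to the
# initial life span; every other node loses one; nodes reaching zero
# are replaced by placeholders (subtree and summary dropped, so the
# span must be re-fetched if queried again).
pine_wither_tick <- function(tree, touched, initial_life = 10L) {
  walk <- function(nd) {
    hit <- FALSE
    for (tr in touched) {
      if (nd$left < tr$end && tr$start < nd$right) { hit <- TRUE; break }
    }
    if (hit) {
      nd$life <- initial_life
    } else {
      nd$life <- nd$life - 1L
      if (nd$life <= 0L && !nd$placeholder) {
        nd$placeholder <- TRUE
        nd$children <- NULL
        nd$summary <- NULL
        nd$direct <- FALSE
        nd$life <- 0L
        return(invisible(NULL))
      }
    }
    if (!is.null(nd$children)) for (ch in nd$children) walk(ch)
    invisible(NULL)
  }
  walk(tree$root)
  pine_relink(tree)
  invisible(tree)
}

#' Audit Pine aggregation conservation
#'
#' Checks, at every node whose children all carry summaries, that the
#' node's summary equals the merge of its children's, and that
#' placeholder nodes are empty.
#'
#' @param tree A `pine_tree`.
#' @param tol Relative tolerance for the additive metrics.
#' @return A list with `ok`, `max_rel_err`, and `nodes_checked`.
#' @export
pine_audit <- function(tree, tol = 1e-9) {
  max_err <- 0
  checked <- 0L
  ok <- TRUE
  rel <- function(a, b) abs(a - b) / max(1, abs(a), abs(b))
  walk <- function(nd) {
    if (nd$placeholder &&
        (!is.null(nd$children) || !is.null(nd$summary))) ok <<- FALSE
    if (is.null(nd$children)) return(invisible(NULL))
    sums <- lapply(nd$children, `[[`, "summary")
    if (!any(vapply(sums, is.null, logical(1))) && !is.null(nd$summary)) {
      m <- summary_merge(sums)
      err <- max(rel(nd$summary$bases, m$bases),
                 rel(nd$summary$sum_values, m$sum_values),
                 rel(nd$summary$sum_squares, m$sum_squares))
      if (!is_empty_summary(m)) {
        err <- max(err, rel(nd$summary$max_value, m$max_value),
                   rel(nd$summary$min_value, m$min_value))
      }
      max_err <<- max(max_err, err)
      checked <<- checked + 1L
      if (err > tol) ok <<- FALSE
    }
    for (ch in nd$children) walk(ch)
    invisible(NULL)
  }
  walk(tree$root)
  list(ok = ok, max_rel_err = max_err, nodes_checked = checked)
}

#' Dump a Pine as depth-annotated text
#'
#' @param tree A `pine_tree`.
#' @return A character vector of lines (deterministic; golden-file
#'   friendly).
#' @export
pine_dump <- function(tree) {
  out <- c(sprintf("pine %s len=%s depth=%d n=%d",
                   tree$chrom, format(tree$chrom_len, scientific = FALSE),
                   tree$depth, tree$config$branching_n))
  walk <- function(nd) {
    pad <- strrep("  ", nd$depth + 1L)
    tag <- if (nd$placeholder) "placeholder" else if (is.null(nd$summary))
      "unloaded" else format(nd$summary)
    out <<- c(out, sprintf("%sd%d [%s,%s) life=%d %s", pad, nd$depth,
                           format(nd$left, scientific = FALSE),
                           format(nd$right, scientific = FALSE), nd$life, tag))
    if (!is.null(nd$children)) for (ch in nd$children) walk(ch)
    invisible(NULL)
  }
  walk(tree$root)
  out
}
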