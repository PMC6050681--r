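# Oak: a weight-balanced key/value tree caching sparse (BED-like) records
# for one chromosome. The leaf fringe is an ordered sequence of keys
# (left/right coordinate pairs) that partitions [0, chrom length)
# exactly. A data key holds two lists: records whose start equals the
# left key, and records spanning across the left key. Placeholder keys
# (empty values) mark genome outside the loaded regions. A binary
# BB[alpha] weight-balanced branch structure is (re)built over the
# fringe after every structural change.
#
# The fringe is a pure function of (loaded interval set, cached record
# table): record starts inside loaded segments delimit the data keys,
# maximal unloaded gaps become placeholder keys. Life spans live on the
# fringe keys; a branch node overlaps a query iff some descendant leaf
# does (its span is the union of theirs), so per-leaf life accounting is
# exactly equivalent to ticking every node.

OAK_ALPHA <- 0.292

#' Build an Oak cache for one chromosome
#'
#' Creates the weight-balanced sparse-record cache from the records
#' fetched for one query region. Every unique record start inside the
#' region becomes a leaf key; records crossing later key boundaries are
#' entered in those keys' span lists; the rest of the chromosome is
#' covered by placeholder keys.
#'
#' @param records A BED record data.frame ([read_bed()]) of records
#'   overlapping `query`.
#' @param query A `genomic_interval`, the loaded region.
#' @param chroms A [chrom_info()] table containing the chromosome.
#' @param alpha Weight-balance parameter of the BB\[alpha\] criterion.
#' @param balance If `FALSE`, a degenerate left-deep chain is built
#'   instead of a balanced tree (a control for
#'   [check_weight_balance()]).
#' @return An environment of class `oak_tree`.
#' @export
oak_build <- function(records, query, chroms, alpha = OAK_ALPHA, balance = TRUE) {
  query <- clamp_to_chromosome(query, chroms)
  len <- chrom_length(chroms, query$chrom)
  tree <- new.env(parent = emptyenv())
  class(tree) <- "oak_tree"
  tree$chrom <- query$chrom
  tree$chrom_len <- len
  tree$alpha <- alpha
  tree$balance <- balance
  tree$records <- empty_bed_table()
  tree$loaded <- empty_iset()
  tree$duplicates <- 0L
  tree$fringe <- NULL
  tree$root <- NULL
  oak_update(tree, query, records)
  tree
}

empty_bed_table <- function() {
  data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
             name = character(0), score = character(0), strand = character(0),
             rest = character(0), ncols = integer(0), id = character(0),
             stringsAsFactors = FALSE)
}

oak_check_records <- function(tree, records) {
  if (nrow(records) == 0L) return(invisible(NULL))
  if (any(records$chrom != tree$chrom)) {
    stop("record on the wrong chromosome for this Oak")
  }
  if (any(records$start < 0) || any(records$end > tree$chrom_len)) {
    stop("record outside chromosome bounds")
  }
  invisible(NULL)
}

#' Loaded regions of an Oak or Pine cache
#' @param tree An `oak_tree`.
#' @return A list of `genomic_interval`s currently loaded.
#' @export
oak_loaded <- function(tree) {
  lapply(seq_len(nrow(tree$loaded)), function(i) {
    genomic_interval(tree$chrom, tree$loaded$start[i], tree$loaded$end[i])
  })
}

#' Update an Oak with a newly fetched region
#'
#' Extends the loaded set by `new_region`, inserts the fetched records
#' (records identical to already-cached ones are silently deduplicated
#' and counted in `tree$duplicates`), rebuilds the affected part of the
#' leaf fringe and re-balances the branch structure. Previously loaded
#' data are untouched; updating with a fully covered region and no new
#' records is a no-op.
#'
#' @param tree An `oak_tree`.
#' @param new_region A `genomic_interval` on the tree's chromosome.
#' @param fetched_records Records overlapping the uncovered part of
#'   `new_region` (as returned by [fetch_sparse()]).
#' @return The tree, invisibly.
#' @export
oak_update <- function(tree, new_region, fetched_records) {
  if (new_region$chrom != tree$chrom) stop("region on the wrong chromosome")
  if (new_region$end > tree$chrom_len) stop("region exceeds chromosome")
  oak_check_records(tree, fetched_records)
  if (nrow(fetched_records) > 0L) {
    dup <- fetched_records$id %in% tree$records$id
    tree$duplicates <- tree$duplicates + sum(dup)
    fresh <- fetched_records[!dup, , drop = FALSE]
    fresh <- fresh[!duplicated(fresh$id), , drop = FALSE]
    tree$records <- sort_bed(rbind(tree$records, fresh))
    rownames(tree$records) <- NULL
  }
  tree$loaded <- iset_union(tree$loaded,
                            data.frame(start = new_region$start,
                                       end = new_region$end))
  oak_rebuild_fringe(tree)
  invisible(tree)
}

# Rebuild the leaf fringe from (loaded, records), carrying life spans
# over from the previous fringe: a key inherits the minimum life of the
# data keys its span overlapped; keys over newly loaded genome start at
# the initial life span.
oak_rebuild_fringe <- function(tree, initial_life = 10L) {
  L <- tree$chrom_len
  recs <- tree$records
  loaded <- tree$loaded
  gaps <- iset_diff(data.frame(start = 0, end = L), loaded)

  lefts <- numeric(0); rights <- numeric(0); ph <- logical(0)
  for (i in seq_len(nrow(loaded))) {
    a <- loaded$start[i]; b <- loaded$end[i]
    starts <- sort(unique(recs$start[recs$start >= a & recs$start < b]))
    bounds <- unique(c(a, starts, b))
    lefts <- c(lefts, bounds[-length(bounds)])
    rights <- c(rights, bounds[-1])
    ph <- c(ph, rep(FALSE, length(bounds) - 1L))
  }
  if (nrow(gaps) > 0L) {
    lefts <- c(lefts, gaps$start); rights <- c(rights, gaps$end)
    ph <- c(ph, rep(TRUE, nrow(gaps)))
  }
  ord <- order(lefts)
  lefts <- lefts[ord]; rights <- rights[ord]; ph <- ph[ord]
  nk <- length(lefts)

  start_idx <- rep(list(integer(0)), nk)
  span_idx <- rep(list(integer(0)), nk)
  if (nrow(recs) > 0L && nk > 0L) {
    key_at <- match(recs$start, lefts)
    hit <- which(!is.na(key_at))
    hit <- hit[!ph[key_at[hit]]]
    sp <- split(hit, key_at[hit])
    start_idx[as.integer(names(sp))] <- sp
    # span lists: data keys whose left boundary lies strictly inside a record
    for (r in seq_len(nrow(recs))) {
      ks <- which(!ph & lefts > recs$start[r] & lefts < recs$end[r])
      for (k in ks) span_idx[[k]] <- c(span_idx[[k]], r)
    }
  }

  life <- rep(initial_life, nk)
  old <- tree$fringe
  if (!is.null(old)) {
    for (k in seq_len(nk)) {
      if (ph[k]) next
      ov <- which(!old$ph & old$left < rights[k] & lefts[k] < old$right)
      if (length(ov)) life[k] <- min(old$life[ov])
    }
  }

  tree$fringe <- list(left = lefts, right = rights, ph = ph,
                      life = as.integer(life),
                      start_idx = start_idx, span_idx = span_idx)
  oak_rebuild_root(tree)
  invisible(tree)
}

# Branch structure over the fringe: offline BB[alpha] construction by
# recursive median split (a whole-tree rank rebuild). `balance = FALSE`
# produces a left-deep chain used as a degenerate control.
oak_rebuild_root <- function(tree) {
  nk <- length(tree$fringe$left)
  build <- function(lo, hi) {
    if (lo == hi) {
      return(list(leaf = TRUE, lo = lo, hi = hi, weight = 1L,
                  left = tree$fringe$left[lo], right = tree$fringe$right[lo]))
    }
    mid <- if (tree$balance) lo + (hi - lo) %/% 2L else lo
    l <- build(lo, mid); r <- build(mid + 1L, hi)
    list(leaf = FALSE, lo = lo, hi = hi, weight = l$weight + r$weight,
         left = l$left, right = r$right, children = list(l, r))
  }
  tree$root <- if (nk > 0L) build(1L, nk) else NULL
  invisible(tree)
}

#' Retrieve cached records overlapping a region
#'
#' Walks the leaf keys overlapping `region`, unions their start and
#' span lists, deduplicates records stored under several keys and
#' returns them sorted by `(start, end, name)`. The region must be
#' fully inside the loaded set; otherwise an error signals that the
#' engine has to fetch first.
#'
#' @param tree An `oak_tree`.
#' @param region A `genomic_interval`.
#' @return A BED record data.frame.
#' @export
oak_retrieve <- function(tree, region) {
  if (region$chrom != tree$chrom) stop("region on the wrong chromosome")
  if (!iset_covers(tree$loaded, region$start, region$end)) {
    stop(sprintf("region %s not fully loaded; fetch before retrieving",
                 format(region)))
  }
  fr <- tree$fringe
  keys <- which(!fr$ph & fr$left < region$end & region$start < fr$right)
  idx <- unique(unlist(c(fr$start_idx[keys], fr$span_idx[keys])))
  out <- tree$records[idx, , drop = FALSE]
  hit <- out$start < region$end & region$start < out$end
  out <- sort_bed(out[hit, , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Check the BB\[alpha\] weight-balance criterion
#'
#' Every branch must satisfy `min(w_l, w_r) >= alpha * (w_l + w_r)`
#' where weights count leaves.
#'
#' @param tree An `oak_tree`.
#' @return A list with `balanced` (logical) and `worst_ratio` (the
#'   smallest child-weight fraction seen; `NA` for trees without
#'   branches).
#' @export
check_weight_balance <- function(tree) {
  worst <- Inf
  ok <- TRUE
  walk <- function(node) {
    if (is.null(node) || isTRUE(node$leaf)) return(invisible(NULL))
    w <- vapply(node$children, `[[`, numeric(1), "weight")
    ratio <- min(w) / sum(w)
    worst <<- min(worst, ratio)
    if (ratio < tree$alpha) ok <<- FALSE
    for (ch in node$children) walk(ch)
    invisible(NULL)
  }
  walk(tree$root)
  list(balanced = ok, worst_ratio = if (is.infinite(worst)) NA_real_ else worst)
}

oak_tree_depth <- function(tree) {
  walk <- function(node) {
    if (is.null(node) || isTRUE(node$leaf)) return(1L)
    1L + max(vapply(node$children, walk, integer(1)))
  }
  walk(tree$root)
}

oak_leaf_count <- function(tree) length(tree$fringe$left)

# Withering tick for one Oak: keys overlapping a touched region reset to
# the initial life span, others lose one; keys reaching zero are evicted
# (their span leaves the loaded set, data keys become part of the
# placeholder gaps, adjacent placeholders merge in the rebuild).
oak_wither_tick <- function(tree, touched, initial_life = 10L) {
  fr <- tree$fringe
  if (length(fr$left) == 0L) return(invisible(tree))
  hit <- rep(FALSE, length(fr$left))
  for (tr in touched) {
    hit <- hit | (fr$left < tr$end & tr$start < fr$right)
  }
  fr$life[hit] <- initial_life
  fr$life[!hit] <- fr$life[!hit] - 1L
  dead <- !fr$ph & fr$life <= 0L
  tree$fringe <- fr
  if (any(dead)) {
    tree$loaded <- iset_diff(tree$loaded,
                             data.frame(start = fr$left[dead],
                                        end = fr$right[dead]))
    oak_rebuild_fringe(tree, initial_life = initial_life)
  }
  invisible(tree)
}

#' Dump an Oak as indented text
#'
#' A deterministic structural dump (key spans, list sizes, life spans)
#' suitable for golden-file comparisons.
#'
#' @param tree An `oak_tree`.
#' @return A character vector of lines.
#' @export
oak_dump <- function(tree) {
  out <- c(sprintf("oak %s len=%s keys=%d loaded=%s dup=%d",
                   tree$chrom, format(tree$chrom_len, scientific = FALSE),
                   oak_leaf_count(tree),
                   paste(sprintf("[%s,%s)", tree$loaded$start, tree$loaded$end),
                         collapse = ""),
                   tree$duplicates))
  walk <- function(node, depth) {
    pad <- strrep("  ", depth)
    if (isTRUE(node$leaf)) {
      k <- node$lo
      fr <- tree$fringe
      if (fr$ph[k]) {
        out <<- c(out, sprintf("%sleaf [%s,%s) placeholder", pad,
                               format(fr$left[k], scientific = FALSE),
                               format(fr$right[k], scientific = FALSE)))
      } else {
        out <<- c(out, sprintf("%sleaf [%s,%s) start=%d span=%d life=%d", pad,
                               format(fr$left[k], scientific = FALSE),
                               format(fr$right[k], scientific = FALSE),
                               length(fr$start_idx[[k]]),
                               length(fr$span_idx[[k]]), fr$life[k]))
      }
    } else {
      out <<- c(out, sprintf("%sbranch [%s,%s) weight=%d", pad,
                             format(node$left, scientific = FALSE),
                             format(node$right, scientific = FALSE),
                             node$weight))
      for (ch in node$children) walk(ch, depth + 1L)
    }
  }
  if (!is.null(tree$root)) walk(tree$root, 1L)
  out
}
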