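# Session orchestration: a query is issued whenever the viewed region
# changes. For every requested track the engine computes the uncovered
# sub-regions, fetches only those from the backend, updates the per-
# chromosome cache tree, extracts the display payload from the cache,
# and finally runs one withering tick over the trees on the queried
# chromosome(s).

#' Open a caching session over a backend
#'
#' @param backend A [data_backend()] with registered tracks.
#' @param config A [pine_config()] used for all dense tracks.
#' @param life_span_initial Life span given to new or re-touched nodes;
#'   data untouched for this many queries are evicted.
#' @return An environment of class `cache_session`.
#' @export
cache_session <- function(backend, config = pine_config(),
                          life_span_initial = 10L) {
  ses <- new.env(parent = emptyenv())
  class(ses) <- "cache_session"
  ses$backend <- backend
  ses$config <- config
  ses$life_span_initial <- as.integer(life_span_initial)
  ses$query_counter <- 0L
  # track_id -> list(kind, trees); trees keyed by chromosome; an
  # interaction track keeps two Oaks per chromosome, one per anchor side
  ses$tracks <- list()
  ses
}

session_track <- function(ses, track_id) {
  tr <- ses$tracks[[track_id]]
  if (is.null(tr)) {
    st <- backend_store(ses$backend, track_id)
    tr <- list(kind = st$kind, trees = list())
    ses$tracks[[track_id]] <- tr
  }
  tr
}

# Fetch the uncovered parts of `region` and fold them into the track's
# Oak for that chromosome (creating it on first contact).
oak_cover <- function(ses, track_id, region, fetch_fun, tree_key = region$chrom) {
  tr <- ses$tracks[[track_id]]
  tree <- tr$trees[[tree_key]]
  if (is.null(tree)) {
    recs <- fetch_fun(region)
    tree <- oak_build(recs, region, ses$backend$chroms)
    ses$tracks[[track_id]]$trees[[tree_key]] <- tree
    return(tree)
  }
  missing <- subtract_covered(region, oak_loaded(tree))
  for (sub in missing) {
    oak_update(tree, sub, fetch_fun(sub))
  }
  if (length(missing) == 0L) {
    # still extend loaded bookkeeping for fully covered queries (no-op)
    oak_update(tree, region, empty_bed_table())
  }
  tree
}

#' Issue one query against the session
#'
#' For each track: the uncovered sub-regions of the viewport are
#' computed with [subtract_covered()], only those are fetched, the tree
#' is updated, and the payload is read from the cache. A single
#' withering tick then ages every tree on the queried chromosome(s).
#' `second_view` supplies the independent bottom axis of a double-layer
#' interaction display; interaction records are cached and fetched when
#' either anchor touches either viewport.
#'
#' @param ses A [cache_session()].
#' @param track_ids Character vector of registered track ids.
#' @param view A [viewport()].
#' @param second_view Optional second [viewport()] (double-layer
#'   displays).
#' @return A `display_payload` list: `query_id`, `view`, `second_view`,
#'   and per-track entries with `kind` and `records` or `profile`.
#' @export
session_query <- function(ses, track_ids, view, second_view = NULL) {
  ses$query_counter <- ses$query_counter + 1L
  backend_set_query(ses$backend, ses$query_counter)
  views <- c(list(view), if (!is.null(second_view)) list(second_view))
  payload <- list(query_id = ses$query_counter, view = view,
                  second_view = second_view, tracks = list())

  for (track_id in track_ids) {
    tr <- session_track(ses, track_id)
    if (tr$kind == "sparse") {
      region <- view$region
      tree <- oak_cover(ses, track_id, region, function(sub) {
        fetch_sparse(ses$backend, track_id, sub)
      })
      payload$tracks[[track_id]] <- list(
        kind = "sparse", records = oak_retrieve(tree, region))
    } else if (tr$kind == "dense") {
      region <- view$region
      tree <- tr$trees[[region$chrom]]
      if (is.null(tree)) {
        tree <- pine_build(ses$backend$chroms, view, ses$config)
        ses$tracks[[track_id]]$trees[[region$chrom]] <- tree
      }
      pine_update(tree, view, ses$backend, track_id)
      payload$tracks[[track_id]] <- list(
        kind = "dense", profile = pine_profile(tree, view))
    } else if (tr$kind == "interaction") {
      recs <- list()
      for (vp in views) {
        for (side in c("anchor1", "anchor2")) {
          key <- paste0(vp$region$chrom, "/", side)
          tree <- oak_cover(ses, track_id, vp$region, function(sub) {
            interaction_as_bed(
              fetch_interaction(ses$backend, track_id, sub, side = side), side)
          }, tree_key = key)
          recs[[length(recs) + 1L]] <- oak_retrieve(tree, vp$region)
        }
      }
      payload$tracks[[track_id]] <- list(
        kind = "interaction", records = bed_as_interaction(do.call(rbind, recs)))
    }
  }

  wither_tick(ses, views)
  class(payload) <- "display_payload"
  payload
}

# Interaction records ride through the Oak machinery as BED-shaped rows
# keyed on the requested anchor; the full paired record is serialized in
# `rest` and restored on the way out.
interaction_as_bed <- function(idf, side) {
  if (nrow(idf) == 0L) return(empty_bed_table())
  a <- if (side == "anchor1") {
    data.frame(chrom = idf$chrom1, start = idf$start1, end = idf$end1)
  } else {
    data.frame(chrom = idf$chrom2, start = idf$start2, end = idf$end2)
  }
  out <- data.frame(chrom = a$chrom, start = a$start, end = a$end,
                    name = "", score = "", strand = "",
                    rest = paste(idf$chrom1, idf$start1, idf$end1, idf$chrom2,
                                 idf$start2, idf$end2, idf$intensity,
                                 sep = "\t"),
                    ncols = 7L, stringsAsFactors = FALSE)
  out$id <- idf$id
  sort_bed(out)
}

bed_as_interaction <- function(bdf) {
  if (is.null(bdf) || nrow(bdf) == 0L) {
    return(read_interactions_text(character(0)))
  }
  bdf <- bdf[!duplicated(bdf$id), , drop = FALSE]
  tab <- do.call(rbind, strsplit(bdf$rest, "\t", fixed = TRUE))
  out <- data.frame(chrom1 = tab[, 1], start1 = as.numeric(tab[, 2]),
                    end1 = as.numeric(tab[, 3]), chrom2 = tab[, 4],
                    start2 = as.numeric(tab[, 5]), end2 = as.numeric(tab[, 6]),
                    intensity = as.numeric(tab[, 7]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom1, out$start1, out$end1, out$chrom2, out$start2,
                   out$end2), , drop = FALSE]
  out$id <- paste(out$chrom1, out$start1, out$end1, out$chrom2, out$start2,
                  out$end2, out$intensity, sep = "\x1f")
  rownames(out) <- NULL
  out
}

read_interactions_text <- function(lines) {
  data.frame(chrom1 = character(0), start1 = numeric(0), end1 = numeric(0),
             chrom2 = character(0), start2 = numeric(0), end2 = numeric(0),
             intensity = numeric(0), id = character(0), stringsAsFactors = FALSE)
}

#' Withering: one eviction tick
#'
#' Called once per [session_query()]. On every tree whose chromosome
#' was queried: nodes overlapping the touched region(s) — and hence all
#' their ancestors — get their life span reset; all other nodes lose
#' one; nodes reaching zero are replaced by placeholders and their data
#' leave the cache, so a later query refetches them. Trees on other
#' chromosomes are left frozen.
#'
#' @param ses A [cache_session()].
#' @param views List of [viewport()]s of the current query.
#' @return The session, invisibly.
#' @export
wither_tick <- function(ses, views) {
  touched <- list()
  for (vp in views) {
    ch <- vp$region$chrom
    touched[[ch]] <- c(touched[[ch]], list(vp$region))
  }
  for (track_id in names(ses$tracks)) {
    tr <- ses$tracks[[track_id]]
    for (key in names(tr$trees)) {
      ch <- sub("/.*$", "", key)
      regions <- touched[[ch]]
      if (is.null(regions)) next
      tree <- tr$trees[[key]]
      if (inherits(tree, "oak_tree")) {
        oak_wither_tick(tree, regions, ses$life_span_initial)
      } else {
        pine_wither_tick(tree, regions, ses$life_span_initial)
      }
    }
  }
  invisible(ses)
}

#' Per-query and cumulative transfer report
#'
#' @param ses A [cache_session()].
#' @return A data.frame with one row per query: `query_id`, `requests`,
#'   `records_sent`, `bases_summarized`, and their running totals.
#' @export
transfer_report <- function(ses) {
  snap <- ledger_snapshot(ses$backend)
  n <- ses$query_counter
  out <- data.frame(query_id = seq_len(n), requests = rep(0L, n),
                    records_sent = rep(0, n), bases_summarized = rep(0, n))
  if (nrow(snap$log) > 0L && n > 0L) {
    out$requests <- tabulate(snap$log$query_id, nbins = n)
    rec <- snap$log$unit == "records"
    rs <- rowsum(cbind(snap$log$n * rec, snap$log$n * !rec),
                 snap$log$query_id)
    idx <- as.integer(rownames(rs))
    out$records_sent[idx] <- rs[, 1]
    out$bases_summarized[idx] <- rs[, 2]
  }
  out$cum_requests <- cumsum(out$requests)
  out$cum_records_sent <- cumsum(out$records_sent)
  out$cum_bases_summarized <- cumsum(out$bases_summarized)
  out
}
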