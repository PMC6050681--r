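# Brute-force reference answers computed directly from the parsed track
# files, bypassing the caches entirely. Used by the audit subcommand and
# the end-to-end equivalence checks: whatever the session serves from
# Oak/Pine after any sequence of updates and evictions must equal these.

#' Brute-force payload for one query
#'
#' Computes the display payload for a query directly from the backend's
#' parsed track tables (overlap scan for sparse and interaction tracks,
#' base-exact span summaries for dense tracks assembled on the same
#' depth grid the cache uses). No ledger entries are recorded and no
#' caching takes place.
#'
#' @param backend A [data_backend()].
#' @param track_ids Track ids to answer.
#' @param view A [viewport()].
#' @param second_view Optional second [viewport()].
#' @param config The [pine_config()] in use.
#' @return A `display_payload`-shaped list.
#' @export
oracle_query <- function(backend, track_ids, view, second_view = NULL,
                         config = pine_config()) {
  views <- c(list(view), if (!is.null(second_view)) list(second_view))
  payload <- list(view = view, second_view = second_view, tracks = list())
  for (track_id in track_ids) {
    st <- backend_store(backend, track_id)
    if (st$kind == "sparse") {
      recs <- scan_sparse(st$table, view$region)
      recs <- sort_bed(recs[!duplicated(recs$id), , drop = FALSE])
      rownames(recs) <- NULL
      payload$tracks[[track_id]] <- list(kind = "sparse", records = recs)
    } else if (st$kind == "dense") {
      payload$tracks[[track_id]] <- list(
        kind = "dense",
        profile = oracle_profile(st$table, backend$chroms, view, config))
    } else {
      hits <- lapply(views, function(vp) {
        scan_interactions(st$table, vp$region, side = "either")
      })
      recs <- do.call(rbind, hits)
      recs <- recs[!duplicated(recs$id), , drop = FALSE]
      recs <- recs[order(recs$chrom1, recs$start1, recs$end1, recs$chrom2,
                         recs$start2, recs$end2), , drop = FALSE]
      rownames(recs) <- NULL
      payload$tracks[[track_id]] <- list(kind = "interaction", records = recs)
    }
  }
  payload
}

# Enumerate the depth-d grid spans (the spans Pine nodes would occupy)
# that overlap `region`, by recursive partition of the chromosome.
grid_spans <- function(chrom_len, region, depth, n) {
  out_l <- numeric(0); out_r <- numeric(0)
  descend <- function(left, right, d) {
    if (left >= region$end || right <= region$start) return(invisible(NULL))
    if (d == depth) {
      out_l <<- c(out_l, left); out_r <<- c(out_r, right)
      return(invisible(NULL))
    }
    parts <- partition_span(left, right, n)
    for (i in seq_len(nrow(parts))) descend(parts$left[i], parts$right[i], d + 1L)
    invisible(NULL)
  }
  descend(0, chrom_len, 0L)
  data.frame(left = out_l, right = out_r)
}

oracle_profile <- function(segments, chroms, view, config) {
  L <- chrom_length(chroms, view$region$chrom)
  d <- pine_depth(L, interval_width(view$region), view$pixel_width, config)
  spans <- grid_spans(L, view$region, d, config$branching_n)
  sums <- lapply(seq_len(nrow(spans)), function(i) {
    scan_summary(segments, genomic_interval(view$region$chrom, spans$left[i],
                                            spans$right[i]))
  })
  profile_from_spans(spans, sums, view)
}

payload_equal <- function(got, want, tol = 1e-9) {
  problems <- character(0)
  for (track_id in names(want$tracks)) {
    g <- got$tracks[[track_id]]
    w <- want$tracks[[track_id]]
    if (is.null(g)) {
      problems <- c(problems, sprintf("%s: missing from payload", track_id))
      next
    }
    if (w$kind %in% c("sparse", "interaction")) {
      gid <- sort(g$records$id); wid <- sort(w$records$id)
      if (!identical(gid, wid)) {
        problems <- c(problems,
                      sprintf("%s: %d records served vs %d expected",
                              track_id, length(gid), length(wid)))
      }
    } else {
      gp <- g$profile; wp <- w$profile
      if (nrow(gp) != nrow(wp) || !identical(gp$gap, wp$gap)) {
        problems <- c(problems, sprintf("%s: profile shape mismatch", track_id))
      } else {
        i <- !wp$gap
        if (any(abs(gp$mean[i] - wp$mean[i]) >
                  tol * pmax(1, abs(wp$mean[i]))) ||
            any(abs(gp$max[i] - wp$max[i]) > tol * pmax(1, abs(wp$max[i]))) ||
            any(abs(gp$min[i] - wp$min[i]) > tol * pmax(1, abs(wp$min[i])))) {
          problems <- c(problems, sprintf("%s: profile values differ", track_id))
        }
      }
    }
  }
  problems
}

#' Audit a session trace against brute-force answers
#'
#' Replays the trace in a fresh session and, at every step, compares
#' the served payload with [oracle_query()]'s direct file-scan answer;
#' also checks Oak weight balance after each step and that the ledger
#' is monotone. This exercises every cache path, including re-fetches
#' after withering evictions.
#'
#' @param backend A [data_backend()] with the tracks registered.
#' @param steps Trace steps.
#' @param config A [pine_config()].
#' @return A list with `ok`, `n_steps`, `mismatches` (character vector
#'   of problems) and `worst_balance`.
#' @export
audit_trace <- function(backend, steps, config = pine_config()) {
  ses <- cache_session(backend, config)
  problems <- character(0)
  worst_balance <- 1
  last_requests <- 0
  for (i in seq_along(steps)) {
    step <- steps[[i]]
    view <- step_view(step)
    second <- step_second_view(step)
    got <- session_query(ses, unlist(step$tracks), view, second)
    want <- oracle_query(backend, unlist(step$tracks), view, second, config)
    pr <- payload_equal(got, want)
    if (length(pr)) {
      problems <- c(problems, sprintf("step %d: %s", i, paste(pr, collapse = "; ")))
    }
    for (tr in ses$tracks) {
      for (tree in tr$trees) {
        if (inherits(tree, "oak_tree")) {
          bal <- check_weight_balance(tree)
          if (!is.na(bal$worst_ratio)) {
            worst_balance <- min(worst_balance, bal$worst_ratio)
          }
          if (!bal$balanced) {
            problems <- c(problems, sprintf("step %d: oak unbalanced", i))
          }
        } else {
          aud <- pine_audit(tree)
          if (!aud$ok) {
            problems <- c(problems,
                          sprintf("step %d: pine conservation violated", i))
          }
        }
      }
    }
    snap <- ledger_snapshot(backend)
    if (snap$requests < last_requests) {
      problems <- c(problems, sprintf("step %d: ledger decreased", i))
    }
    last_requests <- snap$requests
  }
  list(ok = length(problems) == 0L, n_steps = length(steps),
       mismatches = problems, worst_balance = worst_balance)
}
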