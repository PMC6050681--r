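#' In-process data backend with a transfer ledger
#'
#' Stands in for the remote track server: it reads track files, answers
#' region-scoped requests, computes dense-signal summaries server-side
#' and meters every simulated transfer. The ledger counts logical
#' records and bases, not serialized bytes, so transfer-minimization
#' checks are hardware-independent.
#'
#' @param chroms A [chrom_info()] table (or path to a chrom.sizes file).
#' @return An environment of class `data_backend`.
#' @export
data_backend <- function(chroms) {
  if (is.character(chroms)) chroms <- read_chrom_sizes(chroms)
  stopifnot(inherits(chroms, "chrom_info"))
  be <- new.env(parent = emptyenv())
  be$chroms <- chroms
  be$stores <- list()
  be$ledger <- new.env(parent = emptyenv())
  be$ledger$requests <- 0L
  be$ledger$records_sent <- 0
  be$ledger$bases_summarized <- 0
  be$ledger$query_id <- 0L
  ledger_alloc(be$ledger, 256L)
  be$ledger$len <- 0L
  class(be) <- "data_backend"
  be
}

#' Register a track with the backend
#'
#' @param backend A [data_backend()].
#' @param track_id Unique track identifier.
#' @param kind `"sparse"` (BED), `"dense"` (bedGraph) or
#'   `"interaction"` (paired intervals).
#' @param path Path to the track file.
#' @return The backend, invisibly.
#' @export
backend_add_track <- function(backend, track_id, kind, path) {
  kind <- match.arg(kind, c("sparse", "dense", "interaction"))
  table <- switch(kind,
    sparse = read_bed(path, backend$chroms),
    dense = read_bedgraph(path, backend$chroms),
    interaction = read_interactions(path, backend$chroms))
  backend$stores[[track_id]] <- list(track_id = track_id, kind = kind,
                                     source = path, table = table)
  invisible(backend)
}

backend_store <- function(backend, track_id, kinds = NULL) {
  st <- backend$stores[[track_id]]
  if (is.null(st)) stop(sprintf("unknown track: %s", track_id))
  if (!is.null(kinds) && !(st$kind %in% kinds)) {
    stop(sprintf("track %s has kind %s, need %s", track_id, st$kind,
                 paste(kinds, collapse = "/")))
  }
  st
}

#' Tag subsequent ledger entries with a query id
#' @param backend A [data_backend()].
#' @param query_id Integer query counter value.
#' @export
backend_set_query <- function(backend, query_id) {
  backend$ledger$query_id <- as.integer(query_id)
  invisible(backend)
}

# per-request log kept as parallel vectors grown by doubling
ledger_alloc <- function(lg, cap) {
  lg$cap <- cap
  lg$v_query <- integer(cap); lg$v_track <- character(cap)
  lg$v_chrom <- character(cap); lg$v_start <- numeric(cap)
  lg$v_end <- numeric(cap); lg$v_unit <- character(cap)
  lg$v_n <- numeric(cap); lg$v_level <- integer(cap)
  invisible(lg)
}

ledger_log <- function(backend, track_id, region, unit, n, level = NA_integer_) {
  lg <- backend$ledger
  lg$requests <- lg$requests + 1L
  if (unit == "records") lg$records_sent <- lg$records_sent + n
  if (unit == "bases") lg$bases_summarized <- lg$bases_summarized + n
  if (lg$len == lg$cap) {
    keep <- seq_len(lg$len)
    old <- lapply(c("v_query", "v_track", "v_chrom", "v_start", "v_end",
                    "v_unit", "v_n", "v_level"), function(f) lg[[f]][keep])
    ledger_alloc(lg, lg$cap * 2L)
    for (i in seq_along(old)) {
      f <- c("v_query", "v_track", "v_chrom", "v_start", "v_end", "v_unit",
             "v_n", "v_level")[i]
      lg[[f]][keep] <- old[[i]]
    }
  }
  k <- lg$len + 1L
  lg$len <- k
  lg$v_query[k] <- lg$query_id; lg$v_track[k] <- track_id
  lg$v_chrom[k] <- region$chrom; lg$v_start[k] <- region$start
  lg$v_end[k] <- region$end; lg$v_unit[k] <- unit
  lg$v_n[k] <- n; lg$v_level[k] <- level
  invisible(backend)
}

#' Snapshot the transfer ledger
#'
#' @param backend A [data_backend()].
#' @return A list with cumulative `requests`, `records_sent`,
#'   `bases_summarized` and the per-request `log` data.frame.
#' @export
ledger_snapshot <- function(backend) {
  lg <- backend$ledger
  keep <- seq_len(lg$len)
  log <- data.frame(query_id = lg$v_query[keep], track_id = lg$v_track[keep],
                    chrom = lg$v_chrom[keep], start = lg$v_start[keep],
                    end = lg$v_end[keep], unit = lg$v_unit[keep],
                    n = lg$v_n[keep], level = lg$v_level[keep],
                    stringsAsFactors = FALSE)
  list(requests = lg$requests, records_sent = lg$records_sent,
       bases_summarized = lg$bases_summarized, log = log)
}

# pure overlap scans, shared by the metered fetches and the brute-force
# oracle (the oracle bypasses the ledger and the trees entirely)

scan_sparse <- function(table, region) {
  hit <- table$chrom == region$chrom & table$start < region$end &
    region$start < table$end
  table[hit, , drop = FALSE]
}

scan_interactions <- function(table, region, side = c("either", "anchor1", "anchor2")) {
  side <- match.arg(side)
  h1 <- table$chrom1 == region$chrom & table$start1 < region$end &
    region$start < table$end1
  h2 <- table$chrom2 == region$chrom & table$start2 < region$end &
    region$start < table$end2
  hit <- switch(side, either = h1 | h2, anchor1 = h1, anchor2 = h2)
  table[hit, , drop = FALSE]
}

scan_summary <- function(segments, region) {
  hit <- which(segments$chrom == region$chrom &
                 segments$start < region$end &
                 region$start < segments$end)
  if (length(hit) == 0L) return(summary_empty())
  v <- segments$value[hit]
  ov <- pmin(segments$end[hit], region$end) -
    pmax(segments$start[hit], region$start)
  summary_stats(bases = sum(ov),
                sum_values = sum(ov * v),
                sum_squares = sum(ov * v^2),
                max_value = max(v),
                min_value = min(v))
}

#' Fetch sparse records overlapping a region
#'
#' Returns exactly the records whose interval overlaps `region`
#' (half-open semantics) and charges the ledger with the record count.
#'
#' @param backend A [data_backend()].
#' @param track_id A registered sparse track.
#' @param region A `genomic_interval`.
#' @return A BED record data.frame.
#' @export
fetch_sparse <- function(backend, track_id, region) {
  st <- backend_store(backend, track_id, "sparse")
  out <- scan_sparse(st$table, region)
  ledger_log(backend, track_id, region, "records", nrow(out))
  out
}

#' Fetch interaction records touching a region
#'
#' A record is returned when the requested anchor (or either anchor)
#' overlaps `region`; the ledger is charged with the record count.
#'
#' @param backend A [data_backend()].
#' @param track_id A registered interaction track.
#' @param region A `genomic_interval`.
#' @param side Which anchor must overlap: `"either"` (default),
#'   `"anchor1"` or `"anchor2"`.
#' @return An interaction record data.frame.
#' @export
fetch_interaction <- function(backend, track_id, region,
                              side = c("either", "anchor1", "anchor2")) {
  side <- match.arg(side)
  st <- backend_store(backend, track_id, "interaction")
  out <- scan_interactions(st$table, region, side)
  ledger_log(backend, track_id, region, "records", nrow(out))
  out
}

#' Fetch a base-exact signal summary for a region
#'
#' Summarizes the dense track over the data-covered bases inside
#' `region` (gap bases contribute nothing) and charges the ledger with
#' the covered base count.
#'
#' @param backend A [data_backend()].
#' @param track_id A registered dense track.
#' @param region A `genomic_interval`.
#' @param level Optional tree depth recorded in the ledger log, used by
#'   transfer-minimality audits.
#' @return A [summary_stats()].
#' @export
fetch_summary <- function(backend, track_id, region, level = NA_integer_) {
  st <- backend_store(backend, track_id, "dense")
  out <- scan_summary(st$table, region)
  ledger_log(backend, track_id, region, "bases", out$bases, level = level)
  out
}
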