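#' Region summary statistics
#'
#' The five-metric summary carried by every Pine node and returned by the
#' backend for dense tracks: number of data-covered bases, sum of the
#' per-base values, sum of their squares, maximum and minimum. Bases in
#' signal gaps contribute nothing (they are not counted as zeros).
#'
#' @param bases Count of data-covered bases (>= 0).
#' @param sum_values Sum of the value over every covered base.
#' @param sum_squares Sum of squared per-base values.
#' @param max_value,min_value Extremes over covered bases (`NA` when
#'   `bases == 0`).
#' @return A list of class `summary_stats`.
#' @export
summary_stats <- function(bases, sum_values, sum_squares, max_value, min_value) {
  if (bases < 0) stop("bases must be >= 0")
  if (bases == 0) {
    return(structure(list(bases = 0, sum_values = 0, sum_squares = 0,
                          max_value = NA_real_, min_value = NA_real_),
                     class = "summary_stats"))
  }
  if (is.na(max_value) || is.na(min_value) || min_value > max_value) {
    stop("non-empty summary needs min_value <= max_value")
  }
  structure(list(bases = bases, sum_values = sum_values,
                 sum_squares = sum_squares, max_value = max_value,
                 min_value = min_value),
            class = "summary_stats")
}

#' Empty summary (identity element of [summary_merge()])
#' @export
summary_empty <- function() summary_stats(0, 0, 0, NA, NA)

is_empty_summary <- function(s) s$bases == 0

#' Merge summaries of disjoint regions
#'
#' Counts and sums add; extremes take the max of maxima and min of
#' minima. Empty summaries are identity elements, so a fold over child
#' summaries equals the summary of their union.
#'
#' @param parts A list of `summary_stats` over pairwise-disjoint regions.
#' @return A single `summary_stats`.
#' @export
summary_merge <- function(parts) {
  parts <- parts[vapply(parts, function(p) !is_empty_summary(p), logical(1))]
  if (length(parts) == 0L) return(summary_empty())
  summary_stats(
    bases = sum(vapply(parts, `[[`, numeric(1), "bases")),
    sum_values = sum(vapply(parts, `[[`, numeric(1), "sum_values")),
    sum_squares = sum(vapply(parts, `[[`, numeric(1), "sum_squares")),
    max_value = max(vapply(parts, `[[`, numeric(1), "max_value")),
    min_value = min(vapply(parts, `[[`, numeric(1), "min_value"))
  )
}

#' @export
format.summary_stats <- function(x, ...) {
  if (is_empty_summary(x)) return("<summary: empty>")
  sprintf("<summary: bases=%g sum=%g sumsq=%g max=%g min=%g>",
          x$bases, x$sum_values, x$sum_squares, x$max_value, x$min_value)
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}
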