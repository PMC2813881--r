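#' Bound-minus-free reactivity difference profile
#'
#' Subtracts the free-RNA reactivities from the protein-bound
#' reactivities, position by position. Protections appear as negative
#' differences and enhancements as positive differences. Both inputs must
#' be on the normalized scale and in the same smoothing state; masks are
#' unioned.
#'
#' @param bound,free `reactivity_profile`s for the same RNA.
#' @return A `difference_profile` tibble with columns `position`, `delta`,
#'   `masked`.
#' @export
difference_profile <- function(bound, free) {
  if (nrow(bound) != nrow(free) || !all(bound$position == free$position)) {
    abort("bound and free profiles must cover the same positions")
  }
  sb <- isTRUE(attr(bound, "smoothed"))
  sf <- isTRUE(attr(free, "smoothed"))
  if (sb != sf) {
    abort("bound and free profiles must be in the same smoothing state")
  }
  masked <- bound$masked | free$masked
  delta <- bound$reactivity - free$reactivity
  delta[masked] <- NA_real_
  out <- tibble(position = bound$position, delta = delta, masked = masked)
  attr(out, "smoothed") <- sb
  class(out) <- c("difference_profile", class(tibble()))
  out
}

#' Significance threshold for difference calls
#'
#' @param min_abs_delta Minimum absolute reactivity difference called
#'   significant (normalized units); must be > 0.
#' @param multiplier Background multiplier the threshold represents
#'   (the default rule is 2-fold above the mean background difference).
#' @param source How the threshold was obtained (`"default"` or
#'   `"estimated"`).
#' @param degenerate Set when an estimated threshold collapsed to zero.
#' @return A list of class `call_threshold`.
#' @export
call_threshold <- function(min_abs_delta = 0.2, multiplier = 2,
                           source = "default", degenerate = FALSE) {
  if (!degenerate && min_abs_delta <= 0) abort("min_abs_delta must be > 0")
  structure(list(min_abs_delta = min_abs_delta, multiplier = multiplier,
                 source = source, degenerate = degenerate),
            class = "call_threshold")
}

#' @export
print.call_threshold <- function(x, ...) {
  cat("<call_threshold> |delta| >= ", format(x$min_abs_delta),
      " (", x$multiplier, "x mean background, ", x$source, ")\n", sep = "")
  invisible(x)
}

#' Estimate the significance threshold from replicate background differences
#'
#' Given one or more difference profiles computed between replicates of
#' the *same* condition (e.g. free vs. free), sets the significance
#' threshold to `multiplier` times the mean absolute background
#' difference over unmasked positions. With no replicates supplied the
#' conventional default of 0.2 normalized units is returned (unless
#' `strict = TRUE`, in which case missing input is an error).
#'
#' @param replicate_deltas A `difference_profile` or list of them, from
#'   unchanged-condition comparisons; may be `NULL`.
#' @param multiplier Fold-above-background multiplier (default 2).
#' @param strict If `TRUE`, refuse to fall back to the default and flag a
#'   zero background as degenerate rather than erroring.
#' @return A [call_threshold()].
#' @export
estimate_threshold <- function(replicate_deltas = NULL, multiplier = 2,
                               strict = FALSE) {
  if (is.null(replicate_deltas) ||
      (is.list(replicate_deltas) && !is.data.frame(replicate_deltas) &&
       length(replicate_deltas) == 0)) {
    if (strict) abort("no replicate difference profiles supplied (strict mode)")
    return(call_threshold(0.2, multiplier, source = "default"))
  }
  if (is.data.frame(replicate_deltas)) replicate_deltas <- list(replicate_deltas)
  deltas <- unlist(purrr::map(replicate_deltas,
                              ~ .x$delta[!.x$masked & !is.na(.x$delta)]))
  if (length(deltas) == 0) abort("replicate difference profiles are fully masked")
  thr <- multiplier * mean(abs(deltas))
  if (thr == 0) {
    if (!strict) {
      warn("estimated background is zero; falling back to default threshold 0.2")
      return(call_threshold(0.2, multiplier, source = "default"))
    }
    return(call_threshold(0, multiplier, source = "estimated", degenerate = TRUE))
  }
  call_threshold(thr, multiplier, source = "estimated")
}

#' Call significant protections and enhancements
#'
#' Calls every unmasked position whose absolute difference is at or above
#' the threshold (the rule is inclusive: a difference of exactly the
#' threshold is called). Direction follows the sign of the difference:
#' negative = protection, positive = enhancement.
#'
#' @param diff A `difference_profile`.
#' @param threshold A [call_threshold()] or a bare numeric threshold
#'   (default 0.2 normalized units).
#' @return A `change_calls` tibble with columns `position`, `direction`,
#'   `delta`, `magnitude`.
#' @export
call_changes <- function(diff, threshold = call_threshold()) {
  if (is.numeric(threshold)) threshold <- call_threshold(threshold)
  thr <- threshold$min_abs_delta
  if (thr <= 0) abort("significance threshold must be positive")
  keep <- !diff$masked & !is.na(diff$delta) & abs(diff$delta) >= thr
  out <- tibble(
    position = diff$position[keep],
    direction = dplyr::if_else(diff$delta[keep] < 0, "protection", "enhancement"),
    delta = diff$delta[keep],
    magnitude = abs(diff$delta[keep]))
  attr(out, "threshold") <- thr
  class(out) <- c("change_calls", class(tibble()))
  out
}

#' Group significant calls into contiguous regions
#'
#' Calls of the same direction whose gap contains at most `max_gap`
#' intervening positions share a region; the default `max_gap = 1` lets a
#' single masked or no-data site fall inside a footprint without
#' splitting it.
#'
#' @param calls A `change_calls` tibble sorted by position.
#' @param max_gap Maximum number of intervening non-called positions
#'   bridged within one region.
#' @return A tibble with one row per region: `region_id`, `direction`,
#'   `start`, `end`, `n_calls`, `mean_magnitude`. Coordinates are 1-based
#'   inclusive.
#' @export
segment_regions <- function(calls, max_gap = 1) {
  if (nrow(calls) == 0) {
    return(tibble(region_id = integer(), direction = character(),
                  start = integer(), end = integer(), n_calls = integer(),
                  mean_magnitude = double()))
  }
  if (is.unsorted(calls$position)) abort("calls must be sorted by position")
  new_region <- c(TRUE,
                  diff(calls$position) - 1L > max_gap |
                    calls$direction[-1] != calls$direction[-nrow(calls)])
  calls |>
    dplyr::mutate(region_id = cumsum(new_region)) |>
    dplyr::group_by(.data$region_id, .data$direction) |>
    dplyr::summarise(start = min(.data$position), end = max(.data$position),
                     n_calls = dplyr::n(),
                     mean_magnitude = mean(.data$magnitude),
                     .groups = "drop") |>
    dplyr::select("region_id", "direction", "start", "end", "n_calls",
                  "mean_magnitude")
}
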