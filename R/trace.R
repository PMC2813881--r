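#' Integrate per-nucleotide peak areas from a trace
#'
#' Recovers one intensity per nucleotide and channel from an
#' electropherogram-like trace by numerically integrating the signal
#' within +/- 3 peak widths of each expected peak center. Expected centers
#' come from the trace's known peak positions when available (synthetic
#' traces), otherwise they are detected as local maxima of the ladder or
#' plus channel separated by at least half the median spacing. Peaks with
#' no detectable signal in any channel are flagged `missing`, never
#' silently zero-filled.
#'
#' @param trace A `trace` from [simulate_trace()] or [read_trace()].
#' @return A `peak_table` tibble with columns `position`, `elution`,
#'   `width`, `area_plus`, `area_minus`, `flag` (`"ok"`/`"missing"`).
#' @export
integrate_peaks <- function(trace) {
  ch <- trace$channels
  mu <- trace$peak_positions
  if (is.null(mu)) mu <- detect_peaks(trace)
  if (length(mu) == 0) abort("no peak positions known or detectable")
  if (any(diff(mu) <= 0)) {
    abort("peak positions must be strictly increasing (is this a concatenation of traces?)")
  }
  width <- trace$peak_width %||% estimate_peak_width(mu)
  step <- trace$grid_step %||% median(diff(ch$elution))
  half <- 3 * width
  n <- length(mu)
  area_plus <- area_minus <- numeric(n)
  flag <- character(n)
  top <- max(ch$plus_catalyst, ch$minus_catalyst, ch$ladder)
  for (k in seq_len(n)) {
    idx <- which(ch$elution >= mu[k] - half & ch$elution <= mu[k] + half)
    if (length(idx) == 0) {
      flag[k] <- "missing"
      next
    }
    peak_max <- max(ch$plus_catalyst[idx], ch$minus_catalyst[idx], ch$ladder[idx])
    area_plus[k] <- sum(ch$plus_catalyst[idx]) * step
    area_minus[k] <- sum(ch$minus_catalyst[idx]) * step
    flag[k] <- if (top == 0 || peak_max <= 1e-12 * top) "missing" else "ok"
  }
  positions <- trace$positions %||% seq_len(n)
  out <- tibble(position = positions, elution = mu,
                width = rep(width, n), area_plus = area_plus,
                area_minus = area_minus, flag = flag)
  class(out) <- c("peak_table", class(tibble()))
  if (any(flag == "missing")) {
    warn(paste0(sum(flag == "missing"), " peak(s) flagged missing"))
  }
  out
}

detect_peaks <- function(trace) {
  y <- trace$channels$ladder
  if (all(y == 0)) y <- trace$channels$plus_catalyst
  x <- trace$channels$elution
  is_max <- which(diff(sign(diff(y))) == -2) + 1L
  if (length(is_max) < 2) return(x[is_max])
  spacing <- median(diff(x[is_max]))
  keep <- c(TRUE, diff(x[is_max]) >= spacing / 2)
  x[is_max][keep]
}

estimate_peak_width <- function(mu) {
  if (length(mu) < 2) return(1)
  median(diff(mu)) / 8
}

#' Correct exponential signal decay in a peak table
#'
#' Primer-extension readouts lose signal with distance from the primer;
#' the generator models this as a per-peak multiplier `decay_rate^position`.
#' This inverse step divides each integrated area by that factor. Flags
#' are preserved.
#'
#' @param table A `peak_table` from [integrate_peaks()].
#' @param decay_rate Per-peak decay multiplier in `(0, 1]`.
#' @return The corrected `peak_table`.
#' @export
correct_signal_decay <- function(table, decay_rate) {
  if (decay_rate <= 0 || decay_rate > 1) abort("decay_rate must be in (0, 1]")
  if (decay_rate == 1) return(table)
  fac <- decay_rate^(table$position)
  dplyr::mutate(table, area_plus = .data$area_plus / fac,
                area_minus = .data$area_minus / fac)
}

#' Convert a peak table to a cleavage profile
#'
#' @param table A `peak_table`; `missing` rows become masked positions.
#' @return A `cleavage_profile` tibble.
#' @export
as_cleavage_profile <- function(table) {
  new_cleavage_profile(
    tibble(position = table$position,
           plus = table$area_plus,
           minus = table$area_minus,
           masked = table$flag == "missing"))
}
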