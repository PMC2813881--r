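#' Normalization and classification rule set
#'
#' Encodes the quantification conventions used throughout the package:
#' reactivities are scaled so that 1.0 is the mean intensity of the highly
#' reactive reference set, defined as the 8% most reactive nucleotides
#' after first excluding the top 2%; profiles are smoothed over a
#' three-nucleotide window for visualization; and nucleotides at or below
#' one-half the reference mean (0.5 normalized units) are classified
#' solvent inaccessible.
#'
#' @param exclude_top_fraction Fraction of the most reactive nucleotides
#'   excluded before computing the reference mean.
#' @param reference_fraction Fraction of nucleotides (after exclusion)
#'   whose mean defines 1.0.
#' @param smoothing_window Odd window width, nucleotides.
#' @param inaccessible_cutoff Normalized reactivity at or below which a
#'   nucleotide is called solvent inaccessible.
#' @return A list of class `normalization_rule`.
#' @export
normalization_rule <- function(exclude_top_fraction = 0.02,
                               reference_fraction = 0.08,
                               smoothing_window = 3,
                               inaccessible_cutoff = 0.5) {
  if (exclude_top_fraction <= 0 || exclude_top_fraction >= 1 ||
      reference_fraction <= 0 || reference_fraction >= 1) {
    abort("fractions must be strictly between 0 and 1")
  }
  if (smoothing_window < 1 || smoothing_window %% 2 == 0) {
    abort("smoothing_window must be odd and >= 1")
  }
  structure(list(exclude_top_fraction = exclude_top_fraction,
                 reference_fraction = reference_fraction,
                 smoothing_window = as.integer(smoothing_window),
                 inaccessible_cutoff = inaccessible_cutoff),
            class = "normalization_rule")
}

#' Subtract the no-catalyst background channel
#'
#' The control reaction omitting the radical-generating catalyst measures
#' reverse-transcription stops unrelated to cleavage. The net signal is
#' `max(plus - scale * minus, 0)` per nucleotide; positions where the
#' minus channel saturates are masked.
#'
#' @param profile A `cleavage_profile`.
#' @param scale Channel scaling factor applied to the minus channel
#'   (default 1).
#' @param saturation_limit Minus-channel intensity at or above which a
#'   position is considered saturated and masked (default `Inf`).
#' @return A `cleavage_profile` whose `plus` column holds the net signal
#'   and whose `minus` column is zeroed.
#' @export
subtract_background <- function(profile, scale = 1, saturation_limit = Inf) {
  stopifnot(all(c("plus", "minus", "masked") %in% names(profile)))
  saturated <- !is.na(profile$minus) & profile$minus >= saturation_limit
  out <- dplyr::mutate(profile,
                       masked = .data$masked | saturated,
                       plus = pmax(.data$plus - scale * .data$minus, 0),
                       minus = 0)
  attr(out, "background_subtracted") <- TRUE
  out
}

new_reactivity_profile <- function(position, reactivity, masked,
                                   normalization_factor, smoothed = FALSE,
                                   reference_n = NA_integer_) {
  out <- tibble(position = position, reactivity = reactivity, masked = masked)
  attr(out, "normalization_factor") <- normalization_factor
  attr(out, "smoothed") <- smoothed
  attr(out, "reference_n") <- reference_n
  class(out) <- c("reactivity_profile", class(tibble()))
  out
}

#' Normalize raw cleavage intensities to the 0 to ~1.5 reactivity scale
#'
#' Divides all intensities by the mean of the reference set: unmasked
#' intensities are sorted in descending order (ties broken by position),
#' the top `ceil(2% of N)` values are excluded, and the mean of the next
#' `ceil(8% of N)` values is the normalization factor. By construction
#' the mean normalized reactivity of the reference set is exactly 1.0,
#' and typical profiles span 0 to ~1.5.
#'
#' @param profile A `cleavage_profile` (background-subtracted `plus`
#'   channel is used) or any data frame with `position` and an intensity
#'   column named `plus` or `reactivity`.
#' @param rule A [normalization_rule()].
#' @return A `reactivity_profile` tibble (`position`, `reactivity`,
#'   `masked`) carrying the `normalization_factor` as an attribute.
#' @export
normalize_reactivity <- function(profile, rule = normalization_rule()) {
  vals_col <- if ("plus" %in% names(profile)) "plus" else "reactivity"
  masked <- if ("masked" %in% names(profile)) profile$masked else rep(FALSE, nrow(profile))
  vals <- profile[[vals_col]]
  masked <- masked | is.na(vals)
  n <- sum(!masked)
  if (n < 25) {
    abort("need at least 25 unmasked positions so that the 8% reference set is non-empty")
  }
  idx <- which(!masked)
  ord <- idx[order(-vals[idx], idx)]          # stable descending sort
  n_excl <- ceiling(rule$exclude_top_fraction * n)
  n_ref <- ceiling(rule$reference_fraction * n)
  ref_idx <- ord[(n_excl + 1):(n_excl + n_ref)]
  factor <- mean(vals[ref_idx])
  if (!is.finite(factor) || factor <= 0) {
    abort("normalization factor is zero: profile has no signal")
  }
  reactivity <- vals / factor
  reactivity[masked] <- NA_real_
  new_reactivity_profile(profile$position, reactivity, masked,
                         normalization_factor = factor,
                         reference_n = n_ref)
}

#' Smooth a reactivity profile over a centered window
#'
#' Centered moving average used for visualization and difference display.
#' At the sequence ends the window shrinks to the available neighbors;
#' masked positions are excluded from each window's mean (a position whose
#' window is entirely masked stays masked).
#'
#' @param profile A `reactivity_profile`.
#' @param window Odd window width in nucleotides (default 3).
#' @return The smoothed `reactivity_profile` (attribute `smoothed` set).
#' @export
smooth_reactivity <- function(profile, window = 3) {
  if (window %% 2 == 0) abort("smoothing window must be odd")
  half <- (window - 1L) %/% 2L
  n <- nrow(profile)
  r <- profile$reactivity
  sm <- vapply(seq_len(n), function(i) {
    idx <- max(1L, i - half):min(n, i + half)
    v <- r[idx]
    v <- v[!is.na(v)]
    if (length(v) == 0) NA_real_ else mean(v)
  }, numeric(1))
  out <- new_reactivity_profile(profile$position, sm,
                                profile$masked & is.na(sm) | is.na(sm),
                                attr(profile, "normalization_factor"),
                                smoothed = TRUE,
                                attr(profile, "reference_n"))
  out$masked <- is.na(sm)
  out
}

#' Classify solvent-inaccessible nucleotides
#'
#' Flags nucleotides whose normalized reactivity is one-half the
#' reference mean or less (at or below `cutoff`; the rule is inclusive).
#' Masked positions are excluded (`NA`).
#'
#' @param profile A `reactivity_profile`.
#' @param cutoff Normalized reactivity cutoff (default 0.5, i.e. one-half
#'   of the 1.0 reference mean).
#' @return The profile with a logical `inaccessible` column added.
#' @export
classify_inaccessible <- function(profile, cutoff = 0.5) {
  dplyr::mutate(profile,
                inaccessible = dplyr::if_else(.data$masked, NA,
                                              .data$reactivity <= cutoff))
}
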