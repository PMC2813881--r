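#' Plot a reactivity profile
#'
#' Column plot of normalized reactivity versus nucleotide position, with
#' solvent-inaccessible nucleotides (reactivity at or below the cutoff)
#' highlighted.
#'
#' @param object A `reactivity_profile`.
#' @param cutoff Inaccessibility cutoff drawn and used for highlighting.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.reactivity_profile <- function(object, cutoff = 0.5, ...) {
  d <- dplyr::mutate(object,
                     class = dplyr::case_when(
                       .data$masked ~ "no data",
                       .data$reactivity <= cutoff ~ "inaccessible",
                       TRUE ~ "accessible"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$position, y = .data$reactivity,
                                  fill = .data$class)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::geom_hline(yintercept = cutoff, linetype = "dashed",
                        linewidth = 0.3) +
    ggplot2::scale_fill_manual(values = c(accessible = "grey35",
                                          inaccessible = "orange",
                                          `no data` = "grey85")) +
    ggplot2::labs(x = "nucleotide position", y = "normalized reactivity",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a bound-minus-free difference profile
#'
#' Column plot of reactivity differences; significant protections
#' (negative) and enhancements (positive) at the threshold are colored.
#'
#' @param object A `difference_profile`.
#' @param threshold Significance threshold drawn and used for coloring.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.difference_profile <- function(object, threshold = 0.2, ...) {
  d <- dplyr::mutate(object,
                     class = dplyr::case_when(
                       .data$masked ~ "no data",
                       .data$delta <= -threshold ~ "protection",
                       .data$delta >= threshold ~ "enhancement",
                       TRUE ~ "not significant"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$position, y = .data$delta,
                                  fill = .data$class)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::geom_hline(yintercept = c(-threshold, threshold),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::scale_fill_manual(values = c(protection = "red3",
                                          enhancement = "grey50",
                                          `not significant` = "grey80",
                                          `no data` = "grey92")) +
    ggplot2::labs(x = "nucleotide position",
                  y = "bound - free reactivity", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a Hill binding fit
#'
#' Observed fraction bound versus protein concentration (log axis) with
#' the fitted cooperative binding curve.
#'
#' @param object A converged `hill_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.hill_fit <- function(object, ...) {
  d <- object$data
  grid <- tibble(concentration_nM = exp(seq(log(min(d$concentration_nM)),
                                            log(max(d$concentration_nM)),
                                            length.out = 200)))
  grid$fraction_bound <- hill_fraction_bound(grid$concentration_nM, fit = object)
  cf <- coef(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$concentration_nM,
                                  y = .data$fraction_bound)) +
    ggplot2::geom_line(data = grid, color = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "[protein] (nM)", y = "fraction RNA bound",
      subtitle = sprintf("K1/2 = %.3g nM, n = %.2f, R^2 = %.3f",
                         cf[["k_half"]], cf[["n"]], object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Plot electropherogram-like trace channels
#'
#' @param object A `trace`.
#' @param channels Which channels to draw.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.trace <- function(object,
                           channels = c("plus_catalyst", "minus_catalyst",
                                        "ladder"), ...) {
  d <- tidyr::pivot_longer(object$channels, cols = -"elution",
                           names_to = "channel", values_to = "intensity")
  d <- d[d$channel %in% channels, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$elution, y = .data$intensity,
                                  color = .data$channel)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "elution index", y = "fluorescence intensity",
                  color = NULL) +
    ggplot2::theme_minimal()
}
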