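#' Hill model for cooperative protein binding
#'
#' Fraction of RNA bound at protein concentration `p` under the
#' cooperative Hill model `A * p^n / (p^n + k_half^n)`, where `A` is the
#' total fraction of RNA bound at saturation, `n` the apparent Hill
#' coefficient, and `k_half` the protein concentration at half-maximal
#' binding.
#'
#' @param p Protein concentration(s), nM; must be >= 0.
#' @param A Saturating fraction bound.
#' @param n Hill coefficient.
#' @param k_half Half-maximal concentration, nM.
#' @param fit Alternatively, a `hill_fit` supplying `A`, `n`, `k_half`.
#' @return Fraction bound in `[0, A]`, strictly increasing in `p`.
#' @examples
#' hill_fraction_bound(9.7, A = 0.95, n = 2.2, k_half = 9.7)  # A/2
#' @export
hill_fraction_bound <- function(p, A = NULL, n = NULL, k_half = NULL,
                                fit = NULL) {
  if (!is.null(fit)) {
    cf <- coef(fit)
    A <- cf[["A"]]; n <- cf[["n"]]; k_half <- cf[["k_half"]]
  }
  if (any(p < 0)) abort("protein concentration must be >= 0")
  # p^n / (p^n + k^n) written in ratio form for numerical range safety
  r <- (p / k_half)^n
  ifelse(p == 0, 0, A * r / (r + 1))
}

standardize_binding <- function(data) {
  conc_col <- intersect(c("concentration_nM", "concentration", "conc",
                          "protein_concentration"), names(data))[1]
  fb_col <- intersect(c("fraction_bound", "fb", "bound"), names(data))[1]
  if (is.na(conc_col) || is.na(fb_col)) {
    abort("binding data needs a concentration column and a fraction_bound column")
  }
  out <- tibble(concentration_nM = data[[conc_col]],
                fraction_bound = data[[fb_col]])
  if (any(out$concentration_nM <= 0)) abort("concentrations must be strictly positive")
  dplyr::arrange(out, .data$concentration_nM)
}

#' Fit the cooperative Hill binding model
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt) fit of
#' `fraction_bound ~ A * p^n / (p^n + k_half^n)` to a
#' filter-partitioning concentration series. Starting values are chosen
#' robustly without user input: `A` starts at the maximum observed
#' fraction bound, `k_half` at the concentration nearest half-maximal
#' binding, and the Hill coefficient is multi-started at 1, 2 and 3; the
#' best converged start (lowest residual sum of squares) is kept.
#' Parameters are bounded (`A` in (0, 1.1], `n` in (0.2, 6],
#' `k_half` in (0, 1e5] nM) to prevent degenerate solutions on flat data.
#'
#' @param data Data frame with a concentration column (nM) and a
#'   `fraction_bound` column; at least 5 points spanning at least one
#'   decade.
#' @param rna_concentration Optional RNA concentration (nM). The Hill
#'   equation assumes trace RNA; a warning is issued if it exceeds
#'   one-fifth of the fitted `k_half`.
#' @param weights Optional per-point weights for weighted least squares
#'   (default: unweighted).
#' @return A `hill_fit` object with components `coefficients`
#'   (`A`, `n`, `k_half`), `r_squared`, `converged`, `data`, `fitted`,
#'   `residuals`, `n_obs`. Non-convergence from every start yields
#'   `converged = FALSE` with `NA` coefficients, never a silent
#'   best-effort number.
#' @export
fit_hill <- function(data, rna_concentration = NULL, weights = NULL) {
  d <- standardize_binding(data)
  if (nrow(d) < 5) abort("need at least 5 concentration points to fit the Hill model")
  if (max(d$concentration_nM) / min(d$concentration_nM) < 10) {
    abort("concentrations must span at least one decade")
  }
  p <- d$concentration_nM
  y <- d$fraction_bound
  if (is.null(weights)) weights <- rep(1, length(y))

  A0 <- min(max(y), 1.05)
  k0 <- p[which.min(abs(y - A0 / 2))]
  lower <- c(A = 1e-6, n = 0.2 + 1e-9, k_half = 1e-9)
  upper <- c(A = 1.1, n = 6, k_half = 1e5)

  best <- NULL
  for (n0 in c(1, 2, 3)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ A * (p / k_half)^n / ((p / k_half)^n + 1),
        start = list(A = A0, n = n0, k_half = k0),
        lower = lower, upper = upper, weights = weights,
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                             ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }

  if (is.null(best)) {
    out <- structure(
      list(coefficients = c(A = NA_real_, n = NA_real_, k_half = NA_real_),
           r_squared = NA_real_, converged = FALSE, data = d,
           fitted = rep(NA_real_, length(y)),
           residuals = rep(NA_real_, length(y)), n_obs = length(y),
           diagnostics = "no start converged"),
      class = "hill_fit")
    return(out)
  }

  cf <- coef(best$fit)[c("A", "n", "k_half")]
  fitted <- hill_fraction_bound(p, cf[["A"]], cf[["n"]], cf[["k_half"]])
  resid <- y - fitted
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) NA_real_ else 1 - sum(resid^2) / ss_tot
  if (!is.null(rna_concentration) && rna_concentration > cf[["k_half"]] / 5) {
    warn(paste0("RNA concentration (", rna_concentration,
                " nM) exceeds k_half/5; the trace-RNA assumption of the ",
                "Hill equation may not hold"))
  }
  structure(
    list(coefficients = cf, r_squared = r2, converged = TRUE, data = d,
         fitted = fitted, residuals = resid, n_obs = length(y),
         diagnostics = NULL),
    class = "hill_fit")
}

#' Coefficient of determination of a Hill fit
#'
#' `R^2 = 1 - SS_res / SS_tot` of a fit against a dataset (by default the
#' data it was fitted to). Zero-variance data leaves `R^2` undefined and
#' is flagged with a warning.
#'
#' @param fit A converged `hill_fit`.
#' @param data Optional alternative dataset.
#' @return The coefficient of determination (possibly `NA`).
#' @export
goodness_of_fit <- function(fit, data = NULL) {
  if (!fit$converged) abort("fit did not converge; no goodness of fit available")
  if (is.null(data)) return(fit$r_squared)
  d <- standardize_binding(data)
  yhat <- hill_fraction_bound(d$concentration_nM, fit = fit)
  ss_tot <- sum((d$fraction_bound - mean(d$fraction_bound))^2)
  if (ss_tot == 0) {
    warn("zero-variance data: R^2 is undefined")
    return(NA_real_)
  }
  1 - sum((d$fraction_bound - yhat)^2) / ss_tot
}

#' @export
coef.hill_fit <- function(object, ...) object$coefficients

#' @export
print.hill_fit <- function(x, ...) {
  cat("<hill_fit>")
  if (!x$converged) {
    cat(" NOT converged (", x$diagnostics, ")\n", sep = "")
    return(invisible(x))
  }
  cf <- x$coefficients
  cat(sprintf(" A = %.3f, n = %.2f, K1/2 = %.3g nM, R^2 = %.4f (%d points)\n",
              cf[["A"]], cf[["n"]], cf[["k_half"]], x$r_squared, x$n_obs))
  invisible(x)
}

#' @export
predict.hill_fit <- function(object, newdata = NULL, ...) {
  p <- if (is.null(newdata)) object$data$concentration_nM
       else standardize_binding(newdata)$concentration_nM
  hill_fraction_bound(p, fit = object)
}

#' Tidy a Hill fit into a one-row-per-parameter tibble
#'
#' @param x A `hill_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`.
#' @exportS3Method generics::tidy
tidy.hill_fit <- function(x, ...) {
  tibble(term = names(x$coefficients),
         estimate = unname(x$coefficients))
}

#' One-row model summary of a Hill fit
#'
#' @param x A `hill_fit`.
#' @param ... Unused.
#' @return A tibble with `A`, `n`, `k_half_nM`, `r.squared`, `converged`,
#'   `nobs`.
#' @exportS3Method generics::glance
glance.hill_fit <- function(x, ...) {
  tibble(A = x$coefficients[["A"]], n = x$coefficients[["n"]],
         k_half_nM = x$coefficients[["k_half"]], r.squared = x$r_squared,
         converged = x$converged, nobs = x$n_obs)
}

#' Augment binding data with fitted values and residuals
#'
#' @param x A `hill_fit`.
#' @param ... Unused.
#' @return The fitted dataset with `.fitted` and `.resid` columns.
#' @exportS3Method generics::augment
augment.hill_fit <- function(x, ...) {
  dplyr::mutate(x$data, .fitted = x$fitted, .resid = x$residuals)
}
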