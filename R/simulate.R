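#' Simulation settings for synthetic footprinting experiments
#'
#' Parameterizes the generative model standing in for the wet-lab
#' experiment: hydroxyl radical cleavage intensity at each nucleotide is
#' proportional to its solvent accessibility, corrupted by multiplicative
#' lognormal noise (probing intensities are positive and right-skewed),
#' on top of an additive background that is also present in the
#' (-)-catalyst control channel.
#'
#' @param length RNA length in nucleotides.
#' @param intensity_scale Mean plus-channel intensity of a fully exposed
#'   nucleotide, in arbitrary fluorescence units.
#' @param noise_cv Coefficient of variation of the multiplicative
#'   lognormal noise (>= 0). The default 0.05 reflects the tight replicate
#'   agreement of capillary-electrophoresis probing data and is calibrated
#'   so that replicate (free-vs-free) reactivity differences stay well
#'   below the 0.2 significance threshold, as the calling rule assumes.
#' @param background_rate Fraction of `intensity_scale` present in the
#'   no-catalyst background channel, in `[0, 1)`.
#' @param footprint_depth Fractional reduction of accessibility at
#'   protein-contact sites in the bound state, in `(0, 1]`.
#' @param seed Integer seed forwarded to the generators.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(length = 540, intensity_scale = 1000,
                              noise_cv = 0.05, background_rate = 0.10,
                              footprint_depth = 0.8, seed = 1) {
  if (noise_cv < 0) abort("noise_cv must be >= 0")
  if (background_rate < 0 || background_rate >= 1) {
    abort("background_rate must be in [0, 1)")
  }
  if (footprint_depth <= 0 || footprint_depth > 1) {
    abort("footprint_depth must be in (0, 1]")
  }
  if (length < 80) abort("length must be at least 80 nucleotides")
  structure(list(length = as.integer(length),
                 intensity_scale = intensity_scale, noise_cv = noise_cv,
                 background_rate = background_rate,
                 footprint_depth = footprint_depth, seed = as.integer(seed)),
            class = "simulation_config")
}

lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))   # mean exactly 1
}

new_cleavage_profile <- function(df, ...) {
  out <- as_tibble(df)
  attrs <- list(...)
  for (nm in names(attrs)) attr(out, nm) <- attrs[[nm]]
  class(out) <- c("cleavage_profile", class(tibble()))
  out
}

#' Simulate a two-channel hydroxyl radical cleavage profile
#'
#' Draws per-nucleotide raw intensities for the (+)-catalyst and
#' (-)-catalyst channels of one footprinting experiment. The plus-channel
#' intensity at position i is
#' `intensity_scale * accessibility(i) * lognormal(cv) + background`,
#' where the background draw is independent of accessibility (the control
#' channel measures reverse-transcription stops, not cleavage); the minus
#' channel is a background-only draw.
#'
#' @param model An [rna_structure()] with accessibility defined for the
#'   requested state.
#' @param state `"free"` or `"bound"`: which accessibility profile drives
#'   cleavage.
#' @param config A [simulation_config()]. Its `seed` is used unless
#'   overridden via `seed`.
#' @param seed Optional integer overriding `config$seed`.
#' @return A `cleavage_profile` tibble with columns `position`, `plus`,
#'   `minus`, `masked`.
#' @export
simulate_cleavage <- function(model, state = c("free", "bound"),
                              config = simulation_config(length = model$length),
                              seed = NULL) {
  state <- match.arg(state)
  acc <- switch(state, free = model$accessibility_free,
                bound = model$accessibility_bound)
  if (anyNA(acc)) {
    abort(paste0("model has no accessibility defined for the '", state, "' state"))
  }
  seed <- seed %||% config$seed
  L <- model$length
  withr::with_seed(seed, {
    bg_plus <- if (config$background_rate > 0) {
      config$background_rate * config$intensity_scale * lognormal_noise(L, config$noise_cv)
    } else rep(0, L)
    bg_minus <- if (config$background_rate > 0) {
      config$background_rate * config$intensity_scale * lognormal_noise(L, config$noise_cv)
    } else rep(0, L)
    plus <- config$intensity_scale * acc * lognormal_noise(L, config$noise_cv) + bg_plus
    new_cleavage_profile(
      tibble(position = seq_len(L), plus = plus, minus = bg_minus,
             masked = FALSE),
      state = state, seed = seed, rna = model$name)
  })
}

#' Simulate an electropherogram-like trace from a cleavage profile
#'
#' Emulates the primer-extension capillary electrophoresis readout: each
#' nucleotide contributes one Gaussian peak per channel, with peak area
#' equal to the channel intensity attenuated by an exponential signal
#' decay (`decay_rate^position`). A unit-area ladder channel marks every
#' expected peak position.
#'
#' @param profile A `cleavage_profile`.
#' @param peak_spacing Elution-axis distance between adjacent peaks.
#' @param peak_width Gaussian standard deviation of each peak; must be
#'   smaller than `peak_spacing` (rejected otherwise: peaks would fuse).
#' @param decay_rate Per-peak multiplicative signal decay in `(0, 1]`.
#' @param baseline_sd Standard deviation of additive non-negative baseline
#'   noise on the trace grid (0 disables).
#' @param seed Integer seed for the baseline noise.
#' @return A list of class `trace` with `channels` (tibble: `elution`,
#'   `plus_catalyst`, `minus_catalyst`, `ladder`), `peak_positions`,
#'   `positions`, `peak_width`, `peak_spacing`, `decay_rate`.
#' @export
simulate_trace <- function(profile, peak_spacing = 10, peak_width = 1.2,
                           decay_rate = 0.999, baseline_sd = 0, seed = 1) {
  if (peak_width >= peak_spacing) {
    abort("peak_width must be smaller than peak_spacing (overlapping peaks)")
  }
  if (decay_rate <= 0 || decay_rate > 1) abort("decay_rate must be in (0, 1]")
  n <- nrow(profile)
  offset <- 4 * peak_width + peak_spacing
  mu <- offset + (seq_len(n) - 1L) * peak_spacing
  step <- min(1, peak_width / 2)
  grid <- seq(0, max(mu) + offset, by = step)

  peak_train <- function(areas) {
    y <- numeric(length(grid))
    half <- 6 * peak_width
    for (k in seq_len(n)) {
      if (areas[k] == 0) next
      lo <- max(1L, floor((mu[k] - half) / step) + 1L)
      hi <- min(length(grid), ceiling((mu[k] + half) / step) + 1L)
      idx <- lo:hi
      y[idx] <- y[idx] + areas[k] * dnorm(grid[idx], mu[k], peak_width)
    }
    y
  }
  decay <- decay_rate^(profile$position)
  channels <- tibble(
    elution = grid,
    plus_catalyst = peak_train(profile$plus * decay),
    minus_catalyst = peak_train(profile$minus * decay),
    ladder = peak_train(rep(1, n)))
  if (baseline_sd > 0) {
    channels <- withr::with_seed(seed, dplyr::mutate(
      channels,
      dplyr::across(-"elution", ~ pmax(.x + rnorm(length(.x), 0, baseline_sd), 0))))
  }
  structure(list(channels = channels, peak_positions = mu,
                 positions = profile$position, peak_width = peak_width,
                 peak_spacing = peak_spacing, decay_rate = decay_rate,
                 grid_step = step),
            class = "trace")
}

#' @export
print.trace <- function(x, ...) {
  cat("<trace> ", length(x$peak_positions), " peaks, elution axis 0-",
      round(max(x$channels$elution)), " (step ", x$grid_step, ")\n", sep = "")
  invisible(x)
}

#' Simulate a filter-partitioning binding curve under the Hill model
#'
#' Draws fraction-bound observations at the supplied protein
#' concentrations from the cooperative Hill model
#' `A * P^n / (P^n + k_half^n)` plus Gaussian noise, clipped to
#' `[0, 1.05]` (real filter data can slightly overshoot full binding).
#'
#' @param A Total fraction of RNA bound at saturation, in `(0, 1]`.
#' @param n Hill coefficient (> 0).
#' @param k_half Protein concentration at half-maximal binding, nM.
#' @param concentrations Protein concentrations, nM; strictly positive and
#'   non-empty.
#' @param noise_sd Gaussian noise standard deviation in fraction-bound
#'   units.
#' @param seed Integer seed.
#' @return A tibble with columns `concentration_nM`, `fraction_bound`.
#' @examples
#' simulate_binding_curve(0.95, 2.2, 9.7, hill_concentrations(12), seed = 1)
#' @export
simulate_binding_curve <- function(A, n, k_half, concentrations,
                                   noise_sd = 0.02, seed = 1) {
  if (length(concentrations) == 0) abort("concentrations must be non-empty")
  if (any(concentrations <= 0)) abort("concentrations must be > 0")
  if (A <= 0 || A > 1) abort("A must be in (0, 1]")
  conc <- sort(concentrations)
  withr::with_seed(seed, {
    f <- hill_fraction_bound(conc, A = A, n = n, k_half = k_half)
    if (noise_sd > 0) f <- f + rnorm(length(f), 0, noise_sd)
    tibble(concentration_nM = conc,
           fraction_bound = pmin(pmax(f, 0), 1.05))
  })
}

#' Log-spaced protein concentration series
#'
#' @param n_points Number of concentrations.
#' @param from,to Range in nM.
#' @return Numeric vector of `n_points` log-spaced concentrations.
#' @export
hill_concentrations <- function(n_points = 12, from = 0.1, to = 3000) {
  exp(seq(log(from), log(to), length.out = n_points))
}
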