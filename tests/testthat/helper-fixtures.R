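# shared fixtures, built in code at test time

toy_model <- function(length = 120, seed = 42, footprint_depth = 0.8) {
  build_toy_structure(length = length, seed = seed,
                      footprint_depth = footprint_depth)
}

# a reactivity profile directly from given values (already normalized)
reactivity_from_values <- function(values, masked = rep(FALSE, length(values)),
                                   smoothed = FALSE) {
  out <- tibble::tibble(position = seq_along(values),
                        reactivity = ifelse(masked, NA_real_, values),
                        masked = masked)
  attr(out, "normalization_factor") <- 1
  attr(out, "smoothed") <- smoothed
  class(out) <- c("reactivity_profile", class(tibble::tibble()))
  out
}

# a difference profile directly from delta values
difference_from_values <- function(delta, masked = rep(FALSE, length(delta))) {
  out <- tibble::tibble(position = seq_along(delta),
                        delta = ifelse(masked, NA_real_, delta),
                        masked = masked)
  attr(out, "smoothed") <- FALSE
  class(out) <- c("difference_profile", class(tibble::tibble()))
  out
}

# cleavage profile from a bare intensity vector
cleavage_from_values <- function(plus, minus = rep(0, length(plus))) {
  footprintr:::new_cleavage_profile(
    tibble::tibble(position = seq_along(plus), plus = plus, minus = minus,
                   masked = FALSE))
}

hill_true <- list(bI3 = list(k = 9.7, n = 2.2),
                  azoarcus = list(k = 3.0, n = 1.8),
                  rnasep = list(k = 230, n = 2.0),
                  sl = list(k = 1300, n = 1.5))
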