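test_that("background subtraction handles identity, equal-channel, and saturation cases", {
  p <- cleavage_from_values(c(10, 20, 30, 40))
  out <- subtract_background(p)
  expect_equal(out$plus, c(10, 20, 30, 40))        # minus == 0 -> identity
  p2 <- cleavage_from_values(c(10, 20, 30, 40), c(10, 20, 30, 40))
  expect_true(all(subtract_background(p2)$plus == 0))  # plus == minus -> zero
  # net never negative
  p3 <- cleavage_from_values(c(5, 10), c(8, 2))
  expect_equal(subtract_background(p3)$plus, c(0, 8))
  # saturated minus channel positions get masked
  p4 <- cleavage_from_values(c(5, 10, 20), c(1, 900, 2))
  out4 <- subtract_background(p4, saturation_limit = 800)
  expect_equal(out4$masked, c(FALSE, TRUE, FALSE))
})

test_that("background subtraction recovers the background-free simulation within noise", {
  m <- toy_model(150, seed = 5)
  cfg_bg <- simulation_config(length = 150, noise_cv = 0.05, background_rate = 0.1)
  cfg_clean <- simulation_config(length = 150, noise_cv = 0.05, background_rate = 0)
  net <- subtract_background(simulate_cleavage(m, "free", cfg_bg, seed = 21))
  clean <- simulate_cleavage(m, "free", cfg_clean, seed = 22)
  # same generative signal law: relative deviation stays within a few cv
  rel <- (net$plus - clean$plus) / (1000 * m$accessibility_free)
  expect_lt(mean(abs(rel)), 3 * 0.05)
})

test_that("normalization reference mean is exactly 1.0 and the factor matches a hand oracle", {
  # degenerate distribution: 100 equal values all normalize to 1.0
  p <- cleavage_from_values(rep(7.3, 100))
  r <- normalize_reactivity(p)
  expect_true(all(r$reactivity == 1))

  # fixed 50-value profile against an independent sort-and-average oracle
  set.seed(123)
  vals <- runif(50, 0, 100)
  p50 <- cleavage_from_values(vals)
  r50 <- normalize_reactivity(p50)
  sorted <- sort(vals, decreasing = TRUE)
  n_excl <- ceiling(0.02 * 50)                       # 1
  oracle_factor <- mean(sorted[(n_excl + 1):(n_excl + ceiling(0.08 * 50))])  # next 4
  expect_equal(attr(r50, "normalization_factor"), oracle_factor)
  expect_equal(r50$reactivity, vals / oracle_factor)

  # reference-set mean is 1.0 on any simulated profile
  m <- toy_model(540, seed = 9)
  prof <- subtract_background(
    simulate_cleavage(m, "free", simulation_config(), seed = 31))
  rx <- normalize_reactivity(prof)
  f <- attr(rx, "normalization_factor")
  ord <- order(-prof$plus, prof$position)
  ref <- ord[(ceiling(0.02 * 540) + 1):(ceiling(0.02 * 540) + ceiling(0.08 * 540))]
  expect_equal(mean(rx$reactivity[ref]), 1.0)
  expect_error(normalize_reactivity(cleavage_from_values(rep(0, 100))),
               "no signal")
  expect_error(normalize_reactivity(cleavage_from_values(rep(1, 10))),
               "at least 25")
})

test_that("normalization is scale-invariant and idempotent", {
  set.seed(77)
  vals <- rlnorm(200, 5, 0.8)
  r1 <- normalize_reactivity(cleavage_from_values(vals))
  for (c in c(0.01, 3, 1e4)) {
    rc <- normalize_reactivity(cleavage_from_values(c * vals))
    expect_equal(rc$reactivity, r1$reactivity)
  }
  # idempotence: normalizing the normalized output changes nothing
  r2 <- normalize_reactivity(r1)
  expect_equal(r2$reactivity, r1$reactivity)
  expect_equal(attr(r2, "normalization_factor"), 1.0)
})

test_that("masked positions are excluded from normalization statistics", {
  vals <- c(rep(10, 30), 1e6)   # one huge outlier
  p <- cleavage_from_values(vals)
  p$masked[31] <- TRUE
  r <- normalize_reactivity(p)
  expect_true(is.na(r$reactivity[31]))
  expect_equal(r$reactivity[1], 1.0)  # factor computed from the 10s only
})

test_that("smoothing follows the centered shrinking-window rule", {
  # forced cases
  expect_equal(smooth_reactivity(reactivity_from_values(c(0, 3, 0)))$reactivity[2], 1.0)
  expect_equal(smooth_reactivity(reactivity_from_values(c(2, 4, 6, 8)))$reactivity[1], 3.0)
  # constant profile unchanged
  const <- reactivity_from_values(rep(0.8, 20))
  expect_equal(smooth_reactivity(const)$reactivity, rep(0.8, 20))
  expect_error(smooth_reactivity(const, window = 4), "odd")
  # masked positions are excluded from each window mean
  p <- reactivity_from_values(c(1, 2, 100, 4, 5), masked = c(F, F, T, F, F))
  sm <- smooth_reactivity(p)
  expect_equal(sm$reactivity[2], mean(c(1, 2)))
  expect_equal(sm$reactivity[4], mean(c(4, 5)))
})

test_that("smoothing preserves interior means and never leaves the local range", {
  set.seed(5)
  vals <- runif(100, 0, 1.5)
  p <- reactivity_from_values(vals)
  sm <- smooth_reactivity(p)
  # interior mean preserved up to the two boundary exchange terms
  bound <- 2 * max(vals) / (3 * 60)
  expect_lt(abs(mean(sm$reactivity[21:80]) - mean(vals[21:80])), bound)
  # each smoothed value inside [min, max] of its window inputs
  for (i in 2:99) {
    expect_gte(sm$reactivity[i], min(vals[(i - 1):(i + 1)]))
    expect_lte(sm$reactivity[i], max(vals[(i - 1):(i + 1)]))
  }
})

test_that("inaccessibility classification uses the inclusive one-half-mean rule", {
  p <- reactivity_from_values(c(0.49, 0.5, 0.51, NA))
  p$masked[4] <- TRUE
  out <- classify_inaccessible(p)
  expect_equal(out$inaccessible, c(TRUE, TRUE, FALSE, NA))
})

test_that("flagged inaccessible fraction tracks the generator ground truth", {
  m <- toy_model(540, seed = 13)
  truth <- mean(m$accessibility_free <= 0.5)   # ~20% by design
  prof <- subtract_background(
    simulate_cleavage(m, "free", simulation_config(), seed = 41))
  rx <- classify_inaccessible(normalize_reactivity(prof))
  flagged <- mean(rx$inaccessible, na.rm = TRUE)
  expect_lt(abs(flagged - truth), 0.05)
})
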