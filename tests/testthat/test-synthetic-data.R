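test_that("toy structure has two GNRA tetraloop-receptor motifs and is seed-deterministic", {
  for (L in c(80, 120, 540)) {
    m <- build_toy_structure(length = L, seed = 1)
    expect_equal(m$length, L)
    expect_equal(nrow(m$contacts), 2L)
    loops <- find_gnra_tetraloops(m)
    expect_setequal(loops$label, c("L2", "L9"))
    expect_true(all(loops$loop_seq == "GAAA"))
    # contacts reference distinct receptor helices
    expect_equal(length(unique(m$contacts$receptor)), 2L)
    expect_identical(build_toy_structure(length = L, seed = 1),
                     build_toy_structure(length = L, seed = 1))
  }
  expect_error(build_toy_structure(length = 79), "at least 80")
})

test_that("toy structure satisfies the model invariants", {
  m <- toy_model(200, seed = 3)
  # pairs: i < j, each position paired at most once
  expect_true(all(m$pairs$i < m$pairs$j))
  expect_false(any(duplicated(c(m$pairs$i, m$pairs$j))))
  # helix/loop elements are disjoint; element positions + unassigned = L
  struct_pos <- unlist(m$elements$positions[m$elements$kind %in% c("helix", "loop")])
  expect_false(any(duplicated(struct_pos)))
  other_pos <- unlist(m$elements$positions[!m$elements$kind %in% c("helix", "loop")])
  n_unassigned <- m$length - length(unique(unlist(m$elements$positions)))
  expect_equal(length(struct_pos) + length(other_pos) + n_unassigned, m$length)
  # accessibility within [0,1] and bound <= free
  expect_true(all(m$accessibility_free >= 0 & m$accessibility_free <= 1))
  expect_true(all(m$accessibility_bound <= m$accessibility_free + 1e-12))
  # ~20% of positions have low free-state accessibility
  expect_equal(mean(m$accessibility_free <= 0.5), 0.2, tolerance = 0.05)
})

test_that("noise-free cleavage is exactly proportional to accessibility", {
  m <- toy_model(100, seed = 1)
  cfg <- simulation_config(length = 100, intensity_scale = 700, noise_cv = 0,
                           background_rate = 0)
  prof <- simulate_cleavage(m, "free", cfg, seed = 5)
  expect_equal(prof$plus, 700 * m$accessibility_free)
  expect_true(all(prof$minus == 0))
  # accessibility all 1 -> constant plus channel at intensity_scale
  m2 <- m
  m2$accessibility_free <- rep(1, 100)
  prof2 <- simulate_cleavage(m2, "free", cfg, seed = 5)
  expect_true(all(prof2$plus == 700))
})

test_that("bound-state intensity at footprint sites matches the closed-form expectation", {
  depth <- 0.7
  m <- build_toy_structure(length = 100, seed = 2, footprint_depth = depth)
  cfg <- simulation_config(length = 100, intensity_scale = 1000,
                           noise_cv = 0.2, background_rate = 0,
                           footprint_depth = depth)
  fp <- sort(unique(unlist(c(m$contacts$loop_positions,
                             m$contacts$receptor_positions,
                             m$contacts$extension_positions))))
  # closed form: E[plus_bound] = scale * acc_free * (1 - depth) at footprints
  expected <- 1000 * m$accessibility_free[fp] * (1 - depth)
  sims <- vapply(1:1000, function(s) {
    simulate_cleavage(m, "bound", cfg, seed = s)$plus[fp]
  }, numeric(length(fp)))
  got <- rowMeans(sims)
  # lognormal noise has mean 1, so means converge to the closed form
  expect_equal(got, expected, tolerance = 0.03)
})

test_that("expected bound intensity at footprints is monotone in footprint depth", {
  means <- vapply(c(0.2, 0.5, 0.8, 1.0), function(depth) {
    m <- build_toy_structure(length = 100, seed = 2, footprint_depth = depth)
    fp <- unlist(m$contacts$loop_positions)
    cfg <- simulation_config(length = 100, noise_cv = 0.1,
                             background_rate = 0, footprint_depth = depth)
    mean(vapply(1:50, function(s) {
      mean(simulate_cleavage(m, "bound", cfg, seed = s)$plus[fp])
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("cleavage and trace generators are bit-reproducible for a fixed seed", {
  m <- toy_model(100, seed = 1)
  cfg <- simulation_config(length = 100)
  expect_identical(simulate_cleavage(m, "free", cfg, seed = 9),
                   simulate_cleavage(m, "free", cfg, seed = 9))
  p <- simulate_cleavage(m, "free", cfg, seed = 9)
  expect_identical(simulate_trace(p, baseline_sd = 0.5, seed = 4),
                   simulate_trace(p, baseline_sd = 0.5, seed = 4))
  expect_identical(simulate_binding_curve(0.95, 2, 10, hill_concentrations(8),
                                          0.02, seed = 3),
                   simulate_binding_curve(0.95, 2, 10, hill_concentrations(8),
                                          0.02, seed = 3))
})

test_that("binding-curve generator honors the Hill midpoint and saturation limits", {
  # noise-free midpoint identity: fraction bound at k_half is A/2
  d <- simulate_binding_curve(A = 0.9, n = 2.2, k_half = 9.7,
                              concentrations = c(1, 9.7, 100), noise_sd = 0)
  expect_equal(d$fraction_bound[d$concentration_nM == 9.7], 0.45)
  # saturation: at 1000x k_half with n = 2 the curve is within 1e-4 of A
  d2 <- simulate_binding_curve(A = 0.95, n = 2, k_half = 5,
                               concentrations = 5000, noise_sd = 0)
  expect_equal(d2$fraction_bound, 0.95, tolerance = 1e-4 / 0.95)
  # observations are clipped to [0, 1.05]
  d3 <- simulate_binding_curve(A = 1, n = 2, k_half = 1,
                               concentrations = rep(1000, 50),
                               noise_sd = 0.5, seed = 1)
  expect_true(all(d3$fraction_bound >= 0 & d3$fraction_bound <= 1.05))
  expect_error(simulate_binding_curve(0.95, 2, 10, numeric(0)), "non-empty")
})
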