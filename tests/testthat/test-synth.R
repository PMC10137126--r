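test_that("zero-noise, zero-jitter trials equal the Gaussian evoked template", {
  spec <- evoked_only_design(amplitude = -5, peak = 0.155, width = 0.02,
                             n_trials = 3)
  e <- one_cell(spec, seed = 42)
  tmpl <- -5 * exp(-(e$times - 0.155)^2 / (2 * 0.02^2))
  for (i in 1:3) expect_equal(e$data[i, 1, ], tmpl, tolerance = 1e-12)
  avg <- condition_average(e, "attended", "NTP")
  expect_equal(as.numeric(avg$waveform[1, ]), tmpl, tolerance = 1e-12)
})

test_that("first-stimulus locking shifts the template by the stimulus offset", {
  spec <- evoked_only_design(amplitude = 2, peak = 0.17, width = 0.02,
                             locking = "first", n_trials = 1)
  e <- one_cell(spec)
  tmpl <- 2 * exp(-(e$times - (-0.4 + 0.17))^2 / (2 * 0.02^2))
  expect_equal(e$data[1, 1, ], tmpl, tolerance = 1e-12)
})

test_that("degenerate von Mises (huge kappa) gives identical phases across trials", {
  spec <- osc_only_design(kappa = 1e6, n_trials = 8)
  e <- one_cell(spec, seed = 3)
  expect_equal(max(apply(e$data[, 1, ], 2, function(col) diff(range(col)))), 0,
               tolerance = 1e-12)
})

test_that("generated phase concentration matches the Bessel-ratio expectation", {
  # oracle: E[resultant length] of von Mises draws = I1(kappa)/I0(kappa),
  # measured by direct circular statistics on the phases read off at t0
  for (kappa in c(0, 1, 2)) {
    spec <- osc_only_design(kappa = kappa, n_trials = 2000)
    e <- one_cell(spec, seed = 7 + kappa)
    tf <- morlet_decompose(e, freqs_hz = 6)
    phases <- Arg(tf$coeffs[, 1, 1, e$t0_index])
    r_emp <- Mod(mean(exp(1i * phases)))
    # finite-sample oracle: Bessel ratio for kappa > 0, Rayleigh expectation
    # sqrt(pi)/(2 sqrt(n)) of the uniform-phase resultant for kappa = 0
    r_th <- if (kappa == 0) sqrt(pi) / (2 * sqrt(2000))
      else besselI(kappa, 1) / besselI(kappa, 0)
    expect_lt(abs(r_emp - r_th), 0.02, label = sprintf("kappa=%g deviation", kappa))
  }
})

test_that("kappa = 0 phases are circularly uniform (Rayleigh test)", {
  # Rayleigh statistic: under uniformity 2*n*R^2 ~ chi^2(2) asymptotically
  nonsig <- vapply(1:20, function(seed) {
    set.seed(seed)
    ph <- rvonmises(2000, 0, 0)
    R <- Mod(mean(exp(1i * ph)))
    p <- exp(-2000 * R^2)
    p > 0.01
  }, logical(1))
  expect_gte(mean(nonsig), 0.95)
})

test_that("rvonmises draws follow the von Mises distribution (KS check)", {
  set.seed(11)
  kappa <- 2
  ph <- rvonmises(4000, 0, kappa)
  grid <- seq(-pi, pi, length.out = 2001)
  dens <- exp(kappa * cos(grid)) / (2 * pi * besselI(kappa, 0))
  cdf <- cumsum(dens) * diff(grid)[1]
  cdf <- cdf / cdf[length(cdf)]
  emp <- ecdf(ph)(grid)
  expect_lt(max(abs(emp - cdf)), 0.03)
})

test_that("generation is bit-reproducible and stream-stable per (subject, cell)", {
  spec <- default_design("visual", n_subjects = 2, n_trials_per_cell = 4)
  e1 <- generate_subject_epochs(spec, "S01", 99)
  e2 <- generate_subject_epochs(spec, "S01", 99)
  expect_identical(e1$data, e2$data)
  expect_identical(e1$trial_info, e2$trial_info)
  e3 <- generate_subject_epochs(spec, "S02", 99)
  expect_false(identical(e1$data, e3$data))
})

test_that("epochs are additive across component-wise specs (linearity)", {
  # evoked-only + (noise+osc) specs sum to the merged spec when the same
  # streams drive the stochastic parts
  w <- c(OZ = 1)
  ev <- list(evoked_component("N1", 0.155, "second", 0.02, -5, w))
  os <- list(osc_component(6, 2, 0, "second", 2, c(-0.2, 0.4), w))
  spec_ev <- uniform_design(cell_spec(evoked = ev, noise = noise_spec(1, 0)),
                            n_trials = 5)
  spec_os <- uniform_design(cell_spec(oscillations = os, noise = noise_spec(1, 3)),
                            n_trials = 5)
  spec_both <- uniform_design(cell_spec(evoked = ev, oscillations = os,
                                        noise = noise_spec(1, 3)), n_trials = 5)
  a <- generate_subject_epochs(spec_ev, "S01", 5)
  b <- generate_subject_epochs(spec_os, "S01", 5)
  ab <- generate_subject_epochs(spec_both, "S01", 5)
  expect_equal(ab$data, a$data + b$data, tolerance = 1e-12)
})

test_that("1/f noise has the requested variance and spectral slope", {
  set.seed(2)
  nz <- one_over_f_noise(512, 200, 1, 4, 400)
  expect_equal(sd(nz), 4, tolerance = 0.05)
  # average periodogram slope on log-log axes should be near -1
  spec <- rowMeans(Mod(mvfft(nz))^2)[2:200]
  f <- (2:200 - 1) * 200 / 512
  slope <- coef(lm(log(spec) ~ log(f)))[2]
  expect_lt(abs(slope + 1), 0.15)
})

test_that("behavior table obeys the programmed distributions", {
  w <- c(OZ = 1)
  cell <- cell_spec(noise = noise_spec(1, 0),
                    behavior = behavior_spec(1.0, 0.4, 0, 0.08))
  spec <- uniform_design(cell, n_subjects = 2, n_trials = 10)
  bt <- generate_behavior_table(spec, seed = 1)
  expect_true(all(bt$correct))
  expect_true(all(bt$rt_s == 0.4))
  expect_false(anyDuplicated(bt[, c("subject", "ma", "tp", "trial")]) > 0)

  cell2 <- cell_spec(noise = noise_spec(1, 0),
                     behavior = behavior_spec(0.9, 0.4, 0.06, 0.08))
  spec2 <- uniform_design(cell2, n_subjects = 10, n_trials = 170)
  bt2 <- generate_behavior_table(spec2, seed = 8)  # > 10,000 trials
  expect_gt(nrow(bt2), 10000)
  expect_equal(mean(bt2$correct), 0.9, tolerance = 0.01)
  expect_true(all(bt2$rt_s >= 0.08))
})

test_that("spec validation names the offending field", {
  expect_error(evoked_component("x", 0.1, "second", -1, 1, c(OZ = 1)), "width_s")
  expect_error(osc_component(6, -1, 0, "second", 1, c(0, 0.2), c(OZ = 1)),
               "phase_concentration_kappa")
  expect_error(behavior_spec(1.4, 0.3, 0.05, 0.08), "accuracy_prob")
  cells <- setNames(rep(list(cell_spec()), 5), all_cell_keys()[1:5])
  expect_error(design_spec(n_subjects = 1, n_trials_per_cell = 1,
                           channels = "OZ", cells = cells), "cells")
  expect_error(design_spec(n_subjects = 1, n_trials_per_cell = 1,
                           channels = "OZ", first_stim_offset_s = 0.4,
                           cells = setNames(rep(list(cell_spec()), 6),
                                            all_cell_keys())),
               "first_stim_offset_s")
})

test_that("design YAML round-trips and regenerates identical data", {
  spec <- default_design("visual", n_subjects = 1, n_trials_per_cell = 3)
  path <- tempfile(fileext = ".yaml")
  write_design_yaml(spec, path)
  spec2 <- read_design_yaml(path)
  e1 <- generate_subject_epochs(spec, "S01", 4)
  e2 <- generate_subject_epochs(spec2, "S01", 4)
  expect_identical(e1$data, e2$data)
  unlink(path)
})
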