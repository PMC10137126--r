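test_that("Morlet response to a pure sinusoid is flat in amplitude, linear in phase", {
  ts <- (0:599 - 300) / 200
  x <- sin(2 * pi * 10 * ts)
  e <- toy_epochs(array(x, dim = c(1, 1, 600)), t0_index = 301)
  tf <- morlet_decompose(e, freqs_hz = 10)
  ok <- which(tf$valid[1, ])
  mag <- Mod(tf$coeffs[1, 1, 1, ok])
  expect_lt((max(mag) - min(mag)) / mean(mag), 0.02)
  ph <- Arg(tf$coeffs[1, 1, 1, ok])
  rate <- diff(unwrap_phase(ph)) * 200 / (2 * pi)  # Hz
  expect_lt(max(abs(rate - 10)) / 10, 0.01)
})

test_that("zero signal gives zero coefficients; an impulse peaks at its own time", {
  z <- toy_epochs(array(0, dim = c(2, 1, 400)), t0_index = 201)
  tf <- morlet_decompose(z, freqs_hz = c(5, 10))
  expect_equal(max(Mod(tf$coeffs)), 0)

  imp <- array(0, dim = c(1, 1, 400)); imp[1, 1, 201] <- 1
  e <- toy_epochs(imp, t0_index = 201)
  tf <- morlet_decompose(e, freqs_hz = c(4, 8, 16, 32))
  for (f in 1:4) {
    ok <- which(tf$valid[f, ])
    expect_equal(ok[which.max(Mod(tf$coeffs[1, 1, f, ok]))], 201L)
  }
})

test_that("epoch too short for the requested wavelet raises a sizing error", {
  e <- toy_epochs(array(0, dim = c(1, 1, 100)), t0_index = 51)  # 0.5 s
  expect_error(morlet_decompose(e, freqs_hz = 2, n_cycles = 7), "minimum epoch length")
  expect_error(morlet_decompose(e, freqs_hz = 150), "Nyquist")
})

test_that("ITC equals 1 for identical trials and ~0 for antiphase pairs", {
  ts <- (0:399 - 200) / 200
  x <- sin(2 * pi * 8 * ts)
  same <- toy_epochs(array(rep(x, each = 4), dim = c(4, 1, 400)), t0_index = 201)
  m <- itc(morlet_decompose(same, freqs_hz = 8))
  ok <- m$valid[1, ]
  expect_equal(max(abs(m$map[1, 1, ok] - 1)), 0, tolerance = 1e-9)

  anti <- toy_epochs(array(0, dim = c(2, 1, 400)), t0_index = 201)
  anti$data[1, 1, ] <- x; anti$data[2, 1, ] <- -x
  m <- itc(morlet_decompose(anti, freqs_hz = 8))
  expect_lt(max(m$map[1, 1, ok]), 1e-9)
  expect_error(itc(morlet_decompose(toy_epochs(array(0, dim = c(1, 1, 400)),
                                               t0_index = 201), freqs_hz = 8)),
               "2 trials")
})

test_that("band-window ITC recovers the von Mises Bessel-ratio oracle", {
  spec <- osc_only_design(kappa = 2, n_trials = 2000)
  e <- one_cell(spec, seed = 13)
  m <- itc(morlet_decompose(e, freqs_hz = 4:8))
  got <- band_window_mean(m, band_window("theta", c(-0.1, 0.3)))
  expect_lt(abs(got - besselI(2, 1) / besselI(2, 0)), 0.03)
})

test_that("uniform phases give ITC near the Rayleigh expectation", {
  # E[ITC] for N uniform phases is sqrt(pi)/(2 sqrt(N))
  spec <- osc_only_design(kappa = 0, n_trials = 100)
  vals <- sapply(1:5, function(seed) {
    e <- one_cell(spec, seed = seed)
    m <- itc(morlet_decompose(e, freqs_hz = 6))
    band_window_mean(m, band_window("theta", c(-0.1, 0.3)))
  })
  expect_lt(abs(mean(vals) - sqrt(pi) / (2 * sqrt(100))), 0.05)
})

test_that("ITC is amplitude-invariant and bounded in [0, 1]", {
  spec <- osc_only_design(kappa = 1, n_trials = 30, noise_sd = 1)
  e <- one_cell(spec, seed = 9)
  tf <- morlet_decompose(e, freqs_hz = 4:8)
  m1 <- itc(tf)
  expect_true(all(m1$map >= 0 & m1$map <= 1 + 1e-12))
  scaled <- e
  scaled$data <- e$data * rep(runif(n_trials(e), 0.5, 5), times = prod(dim(e$data)[2:3]))
  m2 <- itc(morlet_decompose(scaled, freqs_hz = 4:8))
  expect_equal(m2$map, m1$map, tolerance = 1e-9)
})

test_that("band-window ITC increases with phase concentration", {
  vals <- sapply(c(0, 0.5, 1, 2, 4), function(k) {
    spec <- osc_only_design(kappa = k, n_trials = 400)
    e <- one_cell(spec, seed = 31)
    m <- itc(morlet_decompose(e, freqs_hz = 4:8))
    band_window_mean(m, band_window("theta", c(-0.1, 0.3)))
  })
  expect_true(all(diff(vals) > 0))
})

test_that("ERSP is ~0 dB for stationary input and +3 dB for doubled power", {
  set.seed(14)
  # stationary: white noise trials
  e <- toy_epochs(array(rnorm(60 * 1 * 400), dim = c(60, 1, 400)), t0_index = 251)
  m <- ersp(morlet_decompose(e, freqs_hz = c(10, 20)), c(-0.5, -0.4))
  ok1 <- m$valid[1, ]; ok2 <- m$valid[2, ]
  expect_lt(mean(abs(m$map[1, 1, ok1])), 1.0)   # single-channel sampling noise
  # amplitude doubled post-stimulus in a gated band -> power x4 = +6.02 dB;
  # power doubling checked through an explicit sqrt(2) amplitude step
  ts <- (0:399 - 250) / 200
  osc <- sin(2 * pi * 20 * ts)
  gain <- ifelse(ts >= 0.1 & ts <= 0.5, sqrt(2), 1)
  e2 <- toy_epochs(array(rep(osc * gain, each = 40), dim = c(40, 1, 400)),
                   t0_index = 251)
  m2 <- ersp(morlet_decompose(e2, freqs_hz = 20), c(-0.5, -0.4))
  got <- band_window_mean(m2, band_window("beta", c(0.25, 0.35)))
  expect_equal(got, 10 * log10(2), tolerance = 0.2)
})

test_that("doubling all trial amplitudes leaves ERSP unchanged, x2 post-only adds ~6 dB", {
  spec <- osc_only_design(kappa = 0, n_trials = 40, noise_sd = 2)
  e <- one_cell(spec, seed = 15)
  tf1 <- morlet_decompose(e, freqs_hz = 4:8)
  m1 <- ersp(tf1, c(-0.5, -0.4))
  e2 <- e; e2$data <- 2 * e$data
  m2 <- ersp(morlet_decompose(e2, freqs_hz = 4:8), c(-0.5, -0.4))
  expect_equal(m2$map, m1$map, tolerance = 1e-9)  # baseline ratio cancels gain
})

test_that("vectorized ITC and ERSP equal the naive per-trial loops to 1e-10", {
  spec <- default_design("visual", n_subjects = 1, n_trials_per_cell = 5)
  e <- one_cell(spec, seed = 16, ma = "attended", tp = "VTP")
  tf <- morlet_decompose(e, freqs_hz = c(4, 6, 8))
  m <- itc(tf)
  expect_lt(max(abs(m$map - itc_loop(tf$coeffs))), 1e-10)
  m2 <- ersp(tf, c(-0.5, -0.4))
  ref <- ersp_loop(tf$coeffs, tf$times_s, tf$valid, c(-0.5, -0.4), 200)
  expect_lt(max(abs(m2$map - ref), na.rm = TRUE), 1e-10)
  expect_identical(is.na(m2$map), is.na(ref))
})

test_that("band_window_mean is an unweighted mean over band, window and channels", {
  freqs <- 4:8
  times <- (0:99 - 50) / 200
  map <- array(0, dim = c(1, 5, 100))
  for (k in 1:5) map[1, k, ] <- freqs[k]   # map value = its frequency
  m <- structure(list(map = map, freqs_hz = freqs, times_s = times,
                      valid = matrix(TRUE, 5, 100), channels = "OZ",
                      kind = "itc"), class = "tf_map")
  expect_equal(band_window_mean(m, band_window("theta", c(-0.1, 0.1))), 6)
  const <- m; const$map[] <- 3.5
  expect_equal(band_window_mean(const, band_window("theta", c(-0.1, 0.1))), 3.5)
  none <- m; none$valid[] <- FALSE
  expect_error(band_window_mean(none, band_window("theta", c(-0.1, 0.1))),
               "edge-contaminated")
})

test_that("attended VTP theta ITC drops below MTP at the programmed effect", {
  spec <- default_design("visual", n_subjects = 4, n_trials_per_cell = 20)
  eps <- generate_epochs(spec, 17)
  tab <- build_tf_measure_table(
    eps, itc_windows = list(band_window("theta", c(0.2, 0.3))))
  att <- tab[tab$ma == "attended", ]
  cm <- tapply(att$value, att$tp, mean)
  expect_lt(cm["VTP"], cm["MTP"])
  expect_lt(cm["VTP"], cm["NTP"])
})
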