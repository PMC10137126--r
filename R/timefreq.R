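#' Frequency bands
#'
#' Canonical band limits used throughout: delta 1-3 Hz, theta 4-8 Hz,
#' alpha 8-14 Hz, beta 15-30 Hz.
#'
#' @param band Band name.
#' @return Length-2 numeric `(low_hz, high_hz)`.
#' @export
band_range <- function(band = c("delta", "theta", "alpha", "beta")) {
  band <- match.arg(band)
  switch(band, delta = c(1, 3), theta = c(4, 8), alpha = c(8, 14),
         beta = c(15, 30))
}

#' Band-by-window definition for time-frequency measures
#'
#' @param band One of `"delta"`, `"theta"`, `"alpha"`, `"beta"`.
#' @param window_s Length-2 numeric `(start_s, end_s)` relative to the zero
#'   point.
#' @param name Optional measure label (default `band_start_end`).
#' @return A list of class `band_window`.
#' @export
band_window <- function(band, window_s, name = NULL) {
  rng <- band_range(band)
  if (is.null(name))
    name <- sprintf("%s_%d_%d", band, round(window_s[1] * 1000),
                    round(window_s[2] * 1000))
  structure(list(band = band, range_hz = rng, window_s = window_s, name = name),
            class = "band_window")
}

# Cycle rule: 3 cycles up to 3 Hz, then linearly up to 8 cycles at 40 Hz,
# capped so the truncated wavelet (+-2.5 sd) fits inside the epoch.
default_n_cycles <- function(freqs_hz, epoch_dur_s) {
  cyc <- 3 + (8 - 3) * pmax(0, freqs_hz - 3) / (40 - 3)
  # strict-fit margin keeps the capped wavelet inside the epoch despite
  # floating-point rounding of the duration comparison
  fit_cap <- 2 * pi * freqs_hz * (0.995 * epoch_dur_s) / (2 * MORLET_TRUNC_SD)
  pmin(cyc, fit_cap)
}

MORLET_TRUNC_SD <- 2.5  # wavelet truncated at +-2.5 temporal SDs

# Discrete complex Morlet wavelet at frequency f, unit energy, returned with
# its centre at index 1 and negative-time half wrapped to the tail of an
# nfft-length vector (so FFT-multiplication implements centred convolution).
morlet_wavelet_wrapped <- function(f, n_cycles, sampling_rate, nfft) {
  sigma_t <- n_cycles / (2 * pi * f)
  half <- floor(MORLET_TRUNC_SD * sigma_t * sampling_rate)
  tt <- (-half:half) / sampling_rate
  w <- exp(2i * pi * f * tt) * exp(-tt^2 / (2 * sigma_t^2))
  w <- w / sqrt(sum(Mod(w)^2))
  wv <- complex(length.out = nfft)
  wv[1:(half + 1)] <- w[(half + 1):(2 * half + 1)]
  wv[(nfft - half + 1):nfft] <- w[1:half]
  list(spectrum = stats::fft(wv), half = half)
}

#' Morlet wavelet decomposition of an epoch_set
#'
#' Convolves every trial and channel with complex Morlet wavelets
#' (unit-energy normalisation) via FFT. The number of cycles per frequency
#' defaults to 3 up to 3 Hz rising linearly to 8 at 40 Hz, capped so the
#' truncated wavelet fits inside the epoch. Samples closer to either epoch
#' edge than the wavelet half-support are flagged invalid per frequency and
#' excluded from downstream band-window statistics.
#'
#' @param e An [epoch_set()].
#' @param freqs_hz Frequency grid, Hz (default 1-40 in 1 Hz steps).
#' @param n_cycles Cycles per frequency (scalar or vector); `NULL` for the
#'   default rule.
#' @return A list of class `tf_decomposition`: `coeffs` (complex array
#'   trials x channels x freqs x times), `freqs_hz`, `times_s`, `valid`
#'   (freqs x times logical), `channels`, `method_meta`.
#' @export
morlet_decompose <- function(e, freqs_hz = 1:40, n_cycles = NULL) {
  fs <- e$sampling_rate
  if (max(freqs_hz) >= fs / 2)
    stop(sprintf("max frequency %g Hz is not below Nyquist %g Hz",
                 max(freqs_hz), fs / 2), call. = FALSE)
  if (min(freqs_hz) <= 0) stop("frequencies must be positive", call. = FALSE)
  ns <- n_samples(e)
  dur <- ns / fs
  if (is.null(n_cycles)) n_cycles <- default_n_cycles(freqs_hz, dur)
  n_cycles <- rep_len(n_cycles, length(freqs_hz))
  # wavelet must fit inside the epoch
  wav_dur <- 2 * MORLET_TRUNC_SD * n_cycles / (2 * pi * freqs_hz)
  if (any(wav_dur > dur)) {
    k <- which.max(wav_dur)
    stop(sprintf(paste0("epoch of %.3f s is too short for a %.3g-cycle wavelet ",
                        "at %g Hz: minimum epoch length %.3f s"),
                 dur, n_cycles[k], freqs_hz[k], wav_dur[k]), call. = FALSE)
  }
  d <- dim(e$data)
  max_half <- max(floor(MORLET_TRUNC_SD * (n_cycles / (2 * pi * freqs_hz)) * fs))
  nfft <- stats::nextn(ns + 2 * max_half, 2)
  # forward FFT once over all trial x channel signals
  x <- matrix(0, nfft, d[1] * d[2])
  x[seq_len(ns), ] <- t(matrix(e$data, d[1] * d[2], ns))
  X <- stats::mvfft(x)
  coeffs <- array(complex(1), dim = c(d[1], d[2], length(freqs_hz), ns))
  valid <- matrix(FALSE, length(freqs_hz), ns)
  halfs <- integer(length(freqs_hz))
  for (k in seq_along(freqs_hz)) {
    wk <- morlet_wavelet_wrapped(freqs_hz[k], n_cycles[k], fs, nfft)
    halfs[k] <- wk$half
    yk <- stats::mvfft(X * wk$spectrum, inverse = TRUE)[seq_len(ns), , drop = FALSE] / nfft
    coeffs[, , k, ] <- array(t(yk), dim = c(d[1], d[2], ns))
    if (ns - 2 * wk$half >= 1)
      valid[k, (wk$half + 1):(ns - wk$half)] <- TRUE
  }
  structure(list(coeffs = coeffs, freqs_hz = freqs_hz, times_s = e$times,
                 valid = valid, channels = e$channels,
                 method_meta = list(method = "morlet", n_cycles = n_cycles,
                                    trunc_sd = MORLET_TRUNC_SD,
                                    half_support = halfs,
                                    sampling_rate = fs)),
            class = "tf_decomposition")
}

#' Inter-trial coherence
#'
#' ITC(f, t) is the modulus of the across-trial mean of the unit-normalised
#' complex coefficients: `| (1/N) sum_i F_i(f,t) / |F_i(f,t)| |`. It lies in
#' `[0, 1]`; 1 means every trial has the same phase, and uniform phases give
#' an expectation of `sqrt(pi)/(2 sqrt(N))`. Bins where a trial's
#' coefficient is exactly zero exclude that trial from that bin's `N`.
#'
#' @param tf A `tf_decomposition` from [morlet_decompose()].
#' @return A list of class `tf_map` with `map`
#'   (channels x freqs x times), `freqs_hz`, `times_s`, `valid`, `channels`,
#'   and `kind = "itc"`.
#' @export
itc <- function(tf) {
  d <- dim(tf$coeffs)
  if (d[1] < 2) stop("ITC requires at least 2 trials", call. = FALSE)
  mod <- Mod(tf$coeffs)
  nonzero <- mod > 0
  z <- tf$coeffs
  z[nonzero] <- z[nonzero] / mod[nonzero]
  z[!nonzero] <- 0
  num <- Mod(colSums(z))                     # channels x freqs x times
  nn <- colSums(nonzero)
  map <- array(0, dim = d[2:4])
  pos <- nn > 0
  map[pos] <- num[pos] / nn[pos]
  structure(list(map = map, freqs_hz = tf$freqs_hz, times_s = tf$times_s,
                 valid = tf$valid, channels = tf$channels, kind = "itc"),
            class = "tf_map")
}

#' Event-related spectral perturbation
#'
#' Mean power across trials, expressed in decibels relative to the mean
#' power over a pre-first-stimulus baseline window:
#' `ERSP(f,t) = 10 log10( P(f,t) / B(f) )` with
#' `P(f,t) = (1/N) sum_i |F_i(f,t)|^2` and `B(f)` the mean of `P` over the
#' baseline bins. Only edge-valid baseline bins enter `B(f)`; a frequency
#' with no valid baseline bin yields `NA` with a warning, and a zero
#' baseline power raises an error naming the frequency.
#'
#' @param tf A `tf_decomposition`.
#' @param baseline_window_s Baseline window, seconds (default
#'   `c(-0.5, -0.4)`: the 100 ms before the first stimulus in the default
#'   geometry).
#' @return A `tf_map` with `kind = "ersp"` (values in dB).
#' @export
ersp <- function(tf, baseline_window_s = c(-0.5, -0.4)) {
  d <- dim(tf$coeffs)
  P <- colMeans(Mod(tf$coeffs)^2)            # channels x freqs x times
  bidx <- window_sample_idx(tf$times_s, baseline_window_s,
                            tf$method_meta$sampling_rate %||% infer_rate(tf$times_s))
  map <- array(NA_real_, dim = d[2:4])
  for (k in seq_along(tf$freqs_hz)) {
    bok <- bidx[tf$valid[k, bidx]]
    if (!length(bok)) {
      warning(sprintf("ERSP: no edge-valid baseline bin at %g Hz; returning NA",
                      tf$freqs_hz[k]), call. = FALSE)
      next
    }
    B <- apply(P[, k, bok, drop = FALSE], 1, mean)
    if (any(B == 0))
      stop(sprintf("ERSP: zero baseline power at %g Hz", tf$freqs_hz[k]),
           call. = FALSE)
    Pk <- matrix(P[, k, ], nrow = d[2])
    map[, k, ] <- 10 * log10(Pk / B)
  }
  structure(list(map = map, freqs_hz = tf$freqs_hz, times_s = tf$times_s,
                 valid = tf$valid, channels = tf$channels, kind = "ersp"),
            class = "tf_map")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

infer_rate <- function(times) 1 / stats::median(diff(times))

#' Band-by-window mean of a time-frequency map
#'
#' Unweighted mean over the frequency bins inside the band, the time bins
#' inside the window and the listed channels, restricted to edge-valid bins.
#'
#' @param m A `tf_map` from [itc()] or [ersp()].
#' @param bw A [band_window()].
#' @param channels Channel labels to average (default: all).
#' @return Scalar mean.
#' @export
band_window_mean <- function(m, bw, channels = m$channels) {
  chi <- match(channels, m$channels)
  if (anyNA(chi))
    stop("unknown channel(s): ", paste(channels[is.na(chi)], collapse = ", "),
         call. = FALSE)
  fidx <- which(m$freqs_hz >= bw$range_hz[1] & m$freqs_hz <= bw$range_hz[2])
  if (!length(fidx))
    stop(sprintf("band %s [%g, %g] Hz not covered by the frequency grid",
                 bw$band, bw$range_hz[1], bw$range_hz[2]), call. = FALSE)
  rate <- infer_rate(m$times_s)
  tidx <- window_sample_idx(m$times_s, bw$window_s, rate)
  ok <- m$valid[fidx, tidx, drop = FALSE]
  if (!any(ok))
    stop(sprintf("band-window %s: every bin is edge-contaminated", bw$name),
         call. = FALSE)
  vals <- m$map[chi, fidx, tidx, drop = FALSE]
  okc <- aperm(array(ok, dim = c(length(fidx), length(tidx), length(chi))),
               c(3, 1, 2))
  mean(vals[okc])
}

#' Time-frequency measure table
#'
#' For each subject and MA x TP cell: decompose the cell's trials over the
#' frequencies covering the requested bands, compute ITC and/or ERSP, and
#' take the band-window means over the given channels. One row per
#' subject x cell x measure; ITC measures are named `itc_<band>_<window>`
#' and ERSP measures `ersp_<band>_<window>`.
#'
#' @param epochs Named list of [epoch_set()] per subject.
#' @param itc_windows,ersp_windows Lists of [band_window()] (either may be
#'   empty).
#' @param channels Channels to average.
#' @param baseline_window_s ERSP baseline window.
#' @return Long-format measure table `subject, ma, tp, measure, value`.
#' @export
build_tf_measure_table <- function(epochs, itc_windows = list(),
                                   ersp_windows = list(),
                                   channels = NULL,
                                   baseline_window_s = c(-0.5, -0.4)) {
  band_grid <- function(windows) {
    bands <- unique(vapply(windows, `[[`, "", "band"))
    sort(unique(unlist(lapply(bands, function(b) {
      r <- band_range(b); seq(r[1], r[2], by = 1)
    }))))
  }
  if (!length(itc_windows) && !length(ersp_windows))
    stop("no band windows requested", call. = FALSE)
  freqs_itc <- band_grid(itc_windows)
  freqs_ersp <- band_grid(ersp_windows)
  rows <- list(); i <- 0L
  for (subj in names(epochs)) {
    e <- epochs[[subj]]
    chans <- channels %||% e$channels
    for (ma in unique(e$trial_info$ma)) for (tp in unique(e$trial_info$tp)) {
      cell <- subset_trials(e, e$trial_info$ma == ma & e$trial_info$tp == tp)
      if (length(itc_windows)) {
        m <- itc(morlet_decompose(cell, freqs_hz = freqs_itc))
        for (bw in itc_windows) {
          i <- i + 1L
          rows[[i]] <- data.frame(subject = subj, ma = ma, tp = tp,
                                  measure = paste0("itc_", bw$name),
                                  value = band_window_mean(m, bw, chans),
                                  stringsAsFactors = FALSE)
        }
      }
      if (length(ersp_windows)) {
        m <- ersp(morlet_decompose(cell, freqs_hz = freqs_ersp),
                  baseline_window_s)
        for (bw in ersp_windows) {
          i <- i + 1L
          rows[[i]] <- data.frame(subject = subj, ma = ma, tp = tp,
                                  measure = paste0("ersp_", bw$name),
                                  value = band_window_mean(m, bw, chans),
                                  stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Default ITC / ERSP band windows
#'
#' The analysis windows for this design. ITC: `(-0.30, -0.15)` s around the
#' first-stimulus response, then `(0.10, 0.20)` and `(0.20, 0.30)` s
#' (visual) or `(0.20, 0.40)` s (auditory) after the second stimulus. ERSP:
#' `(-0.20, -0.10)`, `(0.10, 0.20)` and `(0.20, 0.40)` s for both
#' modalities.
#'
#' @param modality `"visual"` or `"auditory"`.
#' @param kind `"itc"` or `"ersp"`.
#' @return List of [band_window()].
#' @export
default_band_windows <- function(modality = c("visual", "auditory"),
                                 kind = c("itc", "ersp")) {
  modality <- match.arg(modality)
  kind <- match.arg(kind)
  if (kind == "itc") {
    if (modality == "visual")
      list(band_window("alpha", c(-0.30, -0.15)),
           band_window("theta", c(0.10, 0.20)),
           band_window("theta", c(0.20, 0.30)))
    else
      list(band_window("delta", c(-0.30, -0.15)),
           band_window("theta", c(0.10, 0.20)),
           band_window("delta", c(0.20, 0.40)))
  } else {
    list(band_window("alpha", c(-0.20, -0.10)),
         band_window("theta", c(0.10, 0.20)),
         band_window("beta", c(0.20, 0.40)))
  }
}
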