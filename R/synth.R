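#' Draw from a von Mises distribution
#'
#' Best-Fisher rejection sampler. `kappa = 0` returns uniform phases on
#' `(-pi, pi]`; `kappa >= 1e5` is treated as the degenerate point mass at
#' `mu` (the acceptance step becomes numerically meaningless there). The
#' expected resultant length of the draws is the Bessel ratio
#' `I1(kappa)/I0(kappa)`.
#'
#' @param n Number of draws.
#' @param mu Mean direction, radians.
#' @param kappa Concentration, `>= 0`.
#' @return Numeric vector of angles in `(-pi, pi]`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 0) {
  if (kappa < 0) stop("'kappa' must be >= 0", call. = FALSE)
  if (n == 0) return(numeric(0))
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  if (kappa >= 1e5) return(rep(wrap_angle(mu), n))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(16L, n - length(out))
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    ccrit <- kappa * (r - f)
    ok <- (ccrit * (2 - ccrit) - u2 > 0) | (log(ccrit / u2) + 1 - ccrit >= 0)
    out <- c(out, sign(u3[ok] - 0.5) * acos(pmin(1, pmax(-1, f[ok]))))
  }
  wrap_angle(mu + out[seq_len(n)])
}

wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

#' Synthesize 1/f background noise
#'
#' Shapes the spectrum of Gaussian white noise in the frequency domain by
#' `f^(-exponent/2)` amplitude gains (DC removed), then inverse-transforms.
#' Columns are independent realisations scaled so their theoretical SD is
#' `sd`, using the analytic gain-power normalisation (no empirical
#' re-scaling, so output is a linear function of the underlying white draw).
#'
#' @param n_samples Samples per realisation.
#' @param sampling_rate Hz.
#' @param exponent Spectral exponent (power ~ 1/f^exponent).
#' @param sd Target standard deviation.
#' @param n_signals Number of independent columns.
#' @return `n_samples x n_signals` matrix.
#' @export
one_over_f_noise <- function(n_samples, sampling_rate, exponent = 1, sd = 1,
                             n_signals = 1) {
  if (sd == 0) return(matrix(0, n_samples, n_signals))
  white <- matrix(stats::rnorm(n_samples * n_signals), n_samples, n_signals)
  if (exponent == 0) return(white * sd)
  freqs <- seq(0, n_samples - 1) * sampling_rate / n_samples
  freqs <- pmin(freqs, sampling_rate - freqs)  # two-sided grid
  g <- c(0, freqs[-1]^(-exponent / 2))
  # var(y_t) = sum(g^2)/n for unit white input; normalise analytically
  g <- g / sqrt(sum(g^2) / n_samples)
  y <- Re(stats::mvfft(stats::mvfft(white) * g, inverse = TRUE)) / n_samples
  y * sd
}

# Deterministic per-(seed, subject, cell) RNG stream id, kept below 2^31 so
# set.seed() accepts it. Adding cells or subjects never perturbs the draws of
# existing ones.
stream_seed <- function(seed, subject_idx, cell_idx, salt = 0L) {
  s <- (as.double(seed) * 2654435761 + subject_idx * 40503 +
          cell_idx * 9973 + salt * 101 + 12345) %% 2147483629
  as.integer(s)
}

gaussian_edge_gate <- function(t, onset, offset, ramp = 0.02) {
  stats::pnorm((t - onset) / ramp) * stats::pnorm((offset - t) / ramp)
}

# Generate all trials of one MA x TP cell for one subject.
generate_cell <- function(spec, ma, tp, subject_id, cell_seed) {
  set.seed(cell_seed)
  cl <- spec$cells[[cell_key(ma, tp)]]
  fs <- spec$sampling_rate
  t0_index <- as.integer(round(-spec$epoch_window[1] * fs)) + 1L
  n_samp <- t0_index + as.integer(round(spec$epoch_window[2] * fs))
  times <- (seq_len(n_samp) - t0_index) / fs
  nt <- spec$n_trials_per_cell
  nch <- length(spec$channels)
  dat <- array(0, dim = c(nt, nch, n_samp))

  lock_time <- function(locking) if (locking == "first") spec$first_stim_offset_s else 0

  for (ev in cl$evoked) {
    wvec <- numeric(nch)
    wvec[match(names(ev$channel_weights), spec$channels)] <- ev$channel_weights
    amp <- ev$amplitude_uv + stats::rnorm(nt, 0, ev$amplitude_jitter_sd_uv)
    lat <- lock_time(ev$locking) + ev$peak_latency_s +
      stats::rnorm(nt, 0, ev$latency_jitter_sd_s)
    # trials x samples template, outer-multiplied over channels
    tmpl <- exp(-(outer(-lat, times, "+"))^2 / (2 * ev$width_s^2)) * amp
    for (ch in which(wvec != 0))
      dat[, ch, ] <- dat[, ch, ] + tmpl * wvec[ch]
  }

  for (os in cl$oscillations) {
    wvec <- numeric(nch)
    wvec[match(names(os$channel_weights), spec$channels)] <- os$channel_weights
    tl <- lock_time(os$locking)
    phase <- rvonmises(nt, os$locked_phase_rad, os$phase_concentration_kappa)
    gate <- gaussian_edge_gate(times - tl, os$envelope[1], os$envelope[2])
    carrier <- outer(phase, 2 * pi * os$center_freq_hz * (times - tl), "+")
    osc <- (cos(carrier) * os$amplitude_uv) * rep(gate, each = nt)
    for (ch in which(wvec != 0))
      dat[, ch, ] <- dat[, ch, ] + osc * wvec[ch]
  }

  if (cl$noise$noise_sd_uv > 0) {
    nz <- one_over_f_noise(n_samp, fs, cl$noise$one_over_f_exponent,
                           cl$noise$noise_sd_uv, nt * nch)
    dat <- dat + aperm(array(nz, dim = c(n_samp, nt, nch)), c(2, 3, 1))
  }

  bh <- cl$behavior
  correct <- stats::runif(nt) < bh$accuracy_prob
  rt <- rtruncnorm_floor(nt, bh$rt_mean_s, bh$rt_sd_s, bh$rt_floor_s)
  ti <- data.frame(subject = subject_id, ma = ma, tp = tp, trial = seq_len(nt),
                   correct = correct, rt_s = rt, stringsAsFactors = FALSE)
  list(data = dat, trial_info = ti, t0_index = t0_index)
}

# Inverse-CDF sampler for a normal truncated below at `floor`.
rtruncnorm_floor <- function(n, mean, sd, floor) {
  if (sd == 0) return(rep(max(mean, floor), n))
  plo <- stats::pnorm((floor - mean) / sd)
  mean + sd * stats::qnorm(plo + stats::runif(n) * (1 - plo))
}

#' Generate one subject's trial-epoched EEG
#'
#' Each trial is the sum of the cell's Gaussian-windowed evoked templates
#' (with per-trial amplitude/latency jitter), its oscillatory components
#' (per-trial phase drawn from von Mises(locked_phase, kappa) at the locking
#' time) and 1/f background noise. Each (subject, cell) pair draws from its
#' own named RNG stream, so the output is reproducible and adding cells or
#' subjects leaves existing draws untouched.
#'
#' @param spec A [design_spec()].
#' @param subject_id Subject label.
#' @param seed Integer master seed.
#' @return An [epoch_set()] with `n_trials_per_cell` trials per MA x TP cell.
#' @export
generate_subject_epochs <- function(spec, subject_id, seed) {
  validate_design_spec(spec)
  sub_idx <- subject_index(spec, subject_id)
  parts <- list(); infos <- list(); t0 <- NULL
  k <- 0L
  for (ma in spec$ma_levels) for (tp in spec$tp_levels) {
    k <- k + 1L
    cell <- generate_cell(spec, ma, tp, subject_id,
                          stream_seed(seed, sub_idx, k))
    parts[[k]] <- cell$data
    infos[[k]] <- cell$trial_info
    t0 <- cell$t0_index
  }
  nt <- vapply(parts, function(p) dim(p)[1], 0L)
  dat <- array(0, dim = c(sum(nt), dim(parts[[1]])[2], dim(parts[[1]])[3]))
  at <- 0L
  for (k in seq_along(parts)) {
    dat[at + seq_len(nt[k]), , ] <- parts[[k]]
    at <- at + nt[k]
  }
  epoch_set(dat, spec$sampling_rate, t0, spec$channels, do.call(rbind, infos))
}

subject_index <- function(spec, subject_id) {
  i <- suppressWarnings(as.integer(sub("^[^0-9]*", "", subject_id)))
  if (is.na(i)) i <- utils::head(which(subject_labels(spec) == subject_id), 1)
  if (length(i) == 0 || is.na(i)) i <- 1L
  i
}

#' Subject labels for a design
#' @param spec A [design_spec()].
#' @return Character vector `S01 ... Snn`.
#' @export
subject_labels <- function(spec) {
  sprintf("S%02d", seq_len(spec$n_subjects))
}

#' Generate epochs for every subject of a design
#'
#' @param spec A [design_spec()].
#' @param seed Integer master seed.
#' @return Named list of [epoch_set()], one per subject.
#' @export
generate_epochs <- function(spec, seed) {
  labs <- subject_labels(spec)
  stats::setNames(lapply(labs, function(s) generate_subject_epochs(spec, s, seed)), labs)
}

#' Generate a long behaviour table
#'
#' One row per subject x MA x TP x trial with a correct flag and a reaction
#' time drawn from the cell's truncated-normal RT distribution. Uses the same
#' named-stream scheme as the EEG generator (a distinct salt keeps the two
#' independent).
#'
#' @param spec A [design_spec()].
#' @param n_subjects Number of subjects (defaults to `spec$n_subjects`).
#' @param seed Integer master seed.
#' @return Data frame with columns `subject, ma, tp, trial, correct, rt_s`.
#' @export
generate_behavior_table <- function(spec, n_subjects = spec$n_subjects, seed) {
  validate_design_spec(spec)
  rows <- list(); i <- 0L
  for (s in seq_len(n_subjects)) {
    k <- 0L
    for (ma in spec$ma_levels) for (tp in spec$tp_levels) {
      k <- k + 1L
      set.seed(stream_seed(seed, s, k, salt = 7L))
      bh <- spec$cells[[cell_key(ma, tp)]]$behavior
      nt <- spec$n_trials_per_cell
      i <- i + 1L
      rows[[i]] <- data.frame(
        subject = sprintf("S%02d", s), ma = ma, tp = tp, trial = seq_len(nt),
        correct = stats::runif(nt) < bh$accuracy_prob,
        rt_s = rtruncnorm_floor(nt, bh$rt_mean_s, bh$rt_sd_s, bh$rt_floor_s),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
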