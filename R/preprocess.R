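#' Preprocessing configuration
#'
#' @param lowpass_hz Low-pass cutoff, Hz.
#' @param target_rate_hz Working sampling rate, Hz.
#' @param anticipation_floor_s Trials with reaction time below this value are
#'   treated as anticipations and rejected, seconds.
#' @param require_correct Keep only correct trials.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(lowpass_hz = 40, target_rate_hz = 200,
                              anticipation_floor_s = 0.080, require_correct = TRUE) {
  if (lowpass_hz >= target_rate_hz / 2)
    stop("invalid preprocess_config: 'lowpass_hz' must be below target Nyquist",
         call. = FALSE)
  structure(list(lowpass_hz = lowpass_hz, target_rate_hz = target_rate_hz,
                 anticipation_floor_s = anticipation_floor_s,
                 require_correct = require_correct),
            class = "preprocess_config")
}

#' Design a linear-phase (Type I) low-pass FIR filter
#'
#' Hamming-window design via [signal::fir1()]; the even order is chosen for a
#' `transition_hz`-wide transition band at the given sampling rate
#' (order ~ 3.3 * fs / transition for a Hamming window).
#'
#' @param cutoff_hz Cutoff frequency, Hz.
#' @param sampling_rate Hz.
#' @param transition_hz Transition-band width, Hz.
#' @return Numeric vector of filter coefficients (odd length).
#' @export
design_lowpass_fir <- function(cutoff_hz, sampling_rate, transition_hz = 10) {
  if (cutoff_hz >= sampling_rate / 2)
    stop(sprintf("cutoff %g Hz is not below the Nyquist frequency %g Hz",
                 cutoff_hz, sampling_rate / 2), call. = FALSE)
  ord <- ceiling(3.3 * sampling_rate / transition_hz)
  if (ord %% 2 == 1) ord <- ord + 1  # even order -> odd-length Type I kernel
  as.numeric(signal::fir1(ord, cutoff_hz / (sampling_rate / 2)))
}

#' Complex frequency response of an FIR filter
#'
#' @param b Filter coefficients.
#' @param freqs_hz Frequencies at which to evaluate.
#' @param sampling_rate Hz.
#' @return Complex vector `H(f)`.
#' @export
fir_response <- function(b, freqs_hz, sampling_rate) {
  k <- seq_along(b) - 1
  vapply(freqs_hz,
         function(f) sum(b * exp(-2i * pi * f / sampling_rate * k)),
         complex(1))
}

# Zero-phase filtering with edge-reflection padding: forward and reverse
# passes of stats::filter, trimmed back to length. Reflection keeps constants
# exactly constant at the boundaries.
filtfilt_padded <- function(x, b) {
  n <- length(x); m <- length(b)
  if (n <= m)
    stop(sprintf("signal of %d samples is too short for a %d-tap filter", n, m),
         call. = FALSE)
  pad <- min(n - 1, 3 * m)
  xp <- c(2 * x[1] - x[pad + 1 - seq_len(pad) + 1], x,
          2 * x[n] - x[n - seq_len(pad)])
  y <- stats::filter(xp, b, sides = 2)
  y <- rev(stats::filter(rev(y), b, sides = 2))
  as.numeric(y[pad + seq_len(n)])
}

apply_fir_epochs <- function(e, b) {
  d <- dim(e$data)
  out <- e$data
  for (i in seq_len(d[1])) for (j in seq_len(d[2]))
    out[i, j, ] <- filtfilt_padded(e$data[i, j, ], b)
  epoch_set(out, e$sampling_rate, e$t0_index, e$channels, e$trial_info)
}

#' Zero-phase FIR low-pass filter an epoch_set
#'
#' Applies the Type-I linear-phase kernel forward and backward (with
#' edge-reflection padding) so component latencies are not shifted. The
#' two-pass application squares the magnitude response: DC gain stays 1
#' within 1e-3 and stop-band attenuation doubles in dB.
#'
#' @param e An [epoch_set()].
#' @param cutoff_hz Cutoff frequency, Hz (must be below Nyquist).
#' @param transition_hz Transition-band width used for the design.
#' @return Filtered [epoch_set()] (same trials, labels and geometry).
#' @export
fir_lowpass <- function(e, cutoff_hz, transition_hz = 10) {
  b <- design_lowpass_fir(cutoff_hz, e$sampling_rate, transition_hz)
  apply_fir_epochs(e, b)
}

#' Integer-factor downsampling with anti-alias filtering
#'
#' The original rate must be an integer multiple of the target. An
#' anti-alias low-pass at 0.4 x target rate is applied first; samples are
#' then decimated on a grid that keeps the zero point on a sample, and times
#' are re-derived from the new rate.
#'
#' @param e An [epoch_set()].
#' @param target_rate_hz Target sampling rate, Hz.
#' @return Downsampled [epoch_set()].
#' @export
downsample <- function(e, target_rate_hz) {
  ratio <- e$sampling_rate / target_rate_hz
  if (abs(ratio - round(ratio)) > 1e-9)
    stop(sprintf("downsample: rate %g Hz is not an integer multiple of target %g Hz",
                 e$sampling_rate, target_rate_hz), call. = FALSE)
  ratio <- as.integer(round(ratio))
  if (ratio == 1L) return(e)
  ef <- fir_lowpass(e, 0.4 * target_rate_hz)
  idx <- seq(((e$t0_index - 1L) %% ratio) + 1L, n_samples(e), by = ratio)
  new_t0 <- which(idx == e$t0_index)
  epoch_set(ef$data[, , idx, drop = FALSE], target_rate_hz, new_t0,
            e$channels, e$trial_info)
}

#' Keep qualified trials
#'
#' A qualified trial is correct (when `require_correct`) and has a reaction
#' time at or above the anticipation floor: button presses earlier than
#' 80 ms after the second stimulus cannot reflect its discrimination and are
#' rejected as anticipations. No upper reaction-time cap is applied.
#'
#' @param e An [epoch_set()].
#' @param cfg A [preprocess_config()].
#' @return A new [epoch_set()]; attribute `"cell_counts"` holds the kept
#'   count per MA x TP cell. A cell present in the input but emptied by the
#'   rule triggers a warning, not an error.
#' @export
select_qualified_trials <- function(e, cfg = preprocess_config()) {
  ti <- e$trial_info
  keep <- ti$rt_s >= cfg$anticipation_floor_s
  if (cfg$require_correct) keep <- keep & ti$correct
  out <- subset_trials(e, keep)
  cells_in <- unique(paste(ti$ma, ti$tp, sep = "."))
  counts <- table(factor(paste(out$trial_info$ma, out$trial_info$tp, sep = "."),
                         levels = cells_in))
  if (any(counts == 0))
    warning("select_qualified_trials: no qualified trials left in cell(s) ",
            paste(names(counts)[counts == 0], collapse = ", "), call. = FALSE)
  attr(out, "cell_counts") <- counts
  out
}

#' Baseline-correct an epoch_set
#'
#' Subtracts, per trial and channel, the mean amplitude over the baseline
#' window. The convention for this design is a 100 ms pre-stimulus baseline
#' per locking stimulus: `(-0.5, -0.4)` s for components locked to the first
#' stimulus and `(-0.1, 0)` s for components locked to the second (the zero
#' point).
#'
#' @param e An [epoch_set()].
#' @param window Length-2 numeric `(start_s, end_s)`; must lie inside the
#'   epoch.
#' @return Baseline-corrected [epoch_set()].
#' @export
baseline_correct <- function(e, window = c(-0.1, 0)) {
  tr <- range(e$times)
  if (window[1] < tr[1] - 0.25 / e$sampling_rate ||
      window[2] > tr[2] + 0.25 / e$sampling_rate)
    stop(sprintf("baseline window [%g, %g] s lies outside the epoch [%g, %g] s",
                 window[1], window[2], tr[1], tr[2]), call. = FALSE)
  idx <- window_sample_idx(e$times, window, e$sampling_rate)
  base <- rowMeans(e$data[, , idx, drop = FALSE], dims = 2)
  out <- e$data - as.vector(base)  # recycles over the sample dimension
  epoch_set(out, e$sampling_rate, e$t0_index, e$channels, e$trial_info)
}

#' Ocular-artifact removal hook
#'
#' Placeholder stage where ICA-based ocular artifact rejection would run on
#' recorded data; synthetic epochs carry no ocular artifacts, so this is the
#' identity.
#'
#' @param e An [epoch_set()].
#' @return `e`, unchanged.
#' @export
remove_ocular_artifacts <- function(e) e
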