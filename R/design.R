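#' @title Design specifications for simulated MA x TP epoched EEG
#' @description Constructors and validators for the generative description of
#'   a two-by-three modality-attention (MA) by timing-prediction (TP)
#'   within-subject study: per-cell evoked components, phase-locked
#'   oscillations, background noise and behavioural distributions.
#' @name design
NULL

#' Create an evoked-component description
#'
#' A Gaussian-windowed monophasic deflection time-locked to one of the two
#' stimuli in a trial. Negative amplitudes describe negativities (N1, N2),
#' positive amplitudes positivities (P2).
#'
#' @param label Component name, e.g. `"N1_second"`.
#' @param peak_latency_s Peak latency in seconds relative to the locking
#'   stimulus onset.
#' @param locking `"first"` or `"second"`: which stimulus the component is
#'   time-locked to. The second stimulus defines the epoch zero point.
#' @param width_s Temporal standard deviation of the Gaussian window, seconds.
#' @param amplitude_uv Peak amplitude in microvolts (signed).
#' @param channel_weights Named numeric vector of per-channel gains in
#'   `[0, 1]`; channels absent from the vector receive 0.
#' @param amplitude_jitter_sd_uv Trial-to-trial SD of the amplitude.
#' @param latency_jitter_sd_s Trial-to-trial SD of the peak latency.
#' @return A list of class `evoked_component`.
#' @export
evoked_component <- function(label, peak_latency_s, locking = c("second", "first"),
                             width_s, amplitude_uv, channel_weights,
                             amplitude_jitter_sd_uv = 0, latency_jitter_sd_s = 0) {
  locking <- match.arg(locking)
  x <- list(label = label, peak_latency_s = peak_latency_s, locking = locking,
            width_s = width_s, amplitude_uv = amplitude_uv,
            channel_weights = channel_weights,
            amplitude_jitter_sd_uv = amplitude_jitter_sd_uv,
            latency_jitter_sd_s = latency_jitter_sd_s)
  class(x) <- "evoked_component"
  if (!is.numeric(width_s) || width_s <= 0)
    stop("invalid evoked_component: 'width_s' must be > 0", call. = FALSE)
  if (length(channel_weights) == 0 || is.null(names(channel_weights)))
    stop("invalid evoked_component: 'channel_weights' must be a nonempty named vector",
         call. = FALSE)
  x
}

#' Create an oscillatory-component description
#'
#' A band-limited oscillation whose phase at the locking stimulus is drawn per
#' trial from a von Mises distribution. `phase_concentration_kappa = 0` gives
#' uniformly random (non-phase-locked) trials; large kappa gives near-perfect
#' phase locking, so the expected inter-trial coherence of the generated
#' phases is the Bessel ratio I1(kappa)/I0(kappa).
#'
#' @param center_freq_hz Oscillation frequency, Hz.
#' @param phase_concentration_kappa von Mises concentration, `>= 0`.
#' @param locked_phase_rad Preferred phase (radians) at the locking time.
#' @param locking `"first"` or `"second"` stimulus.
#' @param amplitude_uv Oscillation amplitude, microvolts.
#' @param envelope Length-2 numeric `(onset_s, offset_s)` of the temporal gate
#'   relative to the locking stimulus; edges are smoothed with a 20 ms
#'   Gaussian ramp to avoid spectral splatter.
#' @param channel_weights Named per-channel gains.
#' @return A list of class `osc_component`.
#' @export
osc_component <- function(center_freq_hz, phase_concentration_kappa,
                          locked_phase_rad = 0, locking = c("second", "first"),
                          amplitude_uv, envelope, channel_weights) {
  locking <- match.arg(locking)
  if (!is.numeric(phase_concentration_kappa) || phase_concentration_kappa < 0)
    stop("invalid osc_component: 'phase_concentration_kappa' must be >= 0",
         call. = FALSE)
  if (!is.numeric(center_freq_hz) || center_freq_hz <= 0)
    stop("invalid osc_component: 'center_freq_hz' must be > 0", call. = FALSE)
  x <- list(center_freq_hz = center_freq_hz,
            phase_concentration_kappa = phase_concentration_kappa,
            locked_phase_rad = locked_phase_rad, locking = locking,
            amplitude_uv = amplitude_uv, envelope = envelope,
            channel_weights = channel_weights)
  class(x) <- "osc_component"
  x
}

#' Background-noise description
#'
#' Broadband noise with a 1/f^exponent power spectrum, synthesised by shaping
#' a white-noise spectrum in the frequency domain.
#'
#' @param one_over_f_exponent Spectral exponent, `>= 0` (0 = white).
#' @param noise_sd_uv Per-channel standard deviation, microvolts.
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(one_over_f_exponent = 1, noise_sd_uv = 0) {
  if (one_over_f_exponent < 0)
    stop("invalid noise_spec: 'one_over_f_exponent' must be >= 0", call. = FALSE)
  if (noise_sd_uv < 0)
    stop("invalid noise_spec: 'noise_sd_uv' must be >= 0", call. = FALSE)
  structure(list(one_over_f_exponent = one_over_f_exponent,
                 noise_sd_uv = noise_sd_uv), class = "noise_spec")
}

#' Behavioural-distribution description
#'
#' @param accuracy_prob Probability that a trial is answered correctly.
#' @param rt_mean_s Mean reaction time, seconds (RT is measured from the
#'   second-stimulus onset to the button press).
#' @param rt_sd_s Reaction-time SD, seconds.
#' @param rt_floor_s Lower truncation of the RT distribution, seconds.
#' @return A list of class `behavior_spec`.
#' @export
behavior_spec <- function(accuracy_prob = 1, rt_mean_s = 0.35, rt_sd_s = 0.06,
                          rt_floor_s = 0.1) {
  if (accuracy_prob < 0 || accuracy_prob > 1)
    stop("invalid behavior_spec: 'accuracy_prob' must be in [0, 1]", call. = FALSE)
  if (rt_floor_s < 0)
    stop("invalid behavior_spec: 'rt_floor_s' must be >= 0", call. = FALSE)
  structure(list(accuracy_prob = accuracy_prob, rt_mean_s = rt_mean_s,
                 rt_sd_s = rt_sd_s, rt_floor_s = rt_floor_s),
            class = "behavior_spec")
}

#' Per-cell generative description
#'
#' @param evoked List of [evoked_component()] (may be empty).
#' @param oscillations List of [osc_component()] (may be empty).
#' @param noise A [noise_spec()].
#' @param behavior A [behavior_spec()].
#' @return A list of class `cell_spec`.
#' @export
cell_spec <- function(evoked = list(), oscillations = list(),
                      noise = noise_spec(), behavior = behavior_spec()) {
  structure(list(evoked = evoked, oscillations = oscillations,
                 noise = noise, behavior = behavior), class = "cell_spec")
}

cell_key <- function(ma, tp) paste(ma, tp, sep = ".")

#' Full design specification
#'
#' Describes the whole simulated study: the 2 x 3 MA x TP factorial cells,
#' epoch geometry, channel montage and per-cell generative content. Epochs
#' are time-locked to the second stimulus (the zero point); the first
#' stimulus precedes it by `-first_stim_offset_s` (400 ms for the analysed
#' inter-stimulus interval).
#'
#' @param ma_levels Two ordered attention labels (default
#'   `c("attended", "unattended")`).
#' @param tp_levels Three ordered timing-prediction labels (default
#'   `c("NTP", "MTP", "VTP")`: no / matched / violated prediction).
#' @param n_subjects Number of simulated subjects.
#' @param n_trials_per_cell Qualified trials generated per MA x TP cell.
#' @param sampling_rate Sampling rate, Hz.
#' @param epoch_window Length-2 numeric `(start_s, end_s)` relative to the
#'   zero point; must contain both stimuli.
#' @param first_stim_offset_s Onset of the first stimulus, seconds (negative).
#' @param channels Ordered channel labels.
#' @param cells Named list of [cell_spec()], one per `ma.tp` combination
#'   (names as produced by `paste(ma, tp, sep = ".")`).
#' @return A list of class `design_spec`.
#' @seealso [default_design()], [null_design()], [generate_subject_epochs()]
#' @export
design_spec <- function(ma_levels = c("attended", "unattended"),
                        tp_levels = c("NTP", "MTP", "VTP"),
                        n_subjects, n_trials_per_cell,
                        sampling_rate = 200, epoch_window = c(-1, 0.8),
                        first_stim_offset_s = -0.4,
                        channels = c("O1", "OZ", "O2"), cells) {
  spec <- structure(list(ma_levels = ma_levels, tp_levels = tp_levels,
                         n_subjects = n_subjects,
                         n_trials_per_cell = n_trials_per_cell,
                         sampling_rate = sampling_rate,
                         epoch_window = epoch_window,
                         first_stim_offset_s = first_stim_offset_s,
                         channels = channels, cells = cells),
                    class = "design_spec")
  validate_design_spec(spec)
  spec
}

#' Validate a design specification
#'
#' @param spec A [design_spec()].
#' @return `spec`, invisibly; errors name the offending field.
#' @export
validate_design_spec <- function(spec) {
  stopifnot(inherits(spec, "design_spec"))
  fail <- function(field, why) stop(sprintf("invalid design_spec: '%s' %s", field, why),
                                    call. = FALSE)
  if (length(spec$ma_levels) != 2) fail("ma_levels", "must have exactly 2 levels")
  if (length(spec$tp_levels) != 3) fail("tp_levels", "must have exactly 3 levels")
  if (!is.numeric(spec$n_subjects) || spec$n_subjects < 1)
    fail("n_subjects", "must be a positive count")
  if (!is.numeric(spec$n_trials_per_cell) || spec$n_trials_per_cell < 1)
    fail("n_trials_per_cell", "must be a positive count")
  if (!is.numeric(spec$sampling_rate) || spec$sampling_rate <= 0)
    fail("sampling_rate", "must be > 0")
  ew <- spec$epoch_window
  if (length(ew) != 2 || ew[1] >= ew[2]) fail("epoch_window", "must be (start, end) with start < end")
  if (!(ew[1] < spec$first_stim_offset_s && spec$first_stim_offset_s < 0))
    fail("first_stim_offset_s", "must lie strictly between epoch start and 0")
  if (ew[2] <= 0) fail("epoch_window", "must extend past the zero point")
  if (length(spec$channels) == 0 || anyDuplicated(spec$channels))
    fail("channels", "must be a nonempty set of unique labels")
  want <- as.vector(outer(spec$ma_levels, spec$tp_levels, cell_key))
  if (!setequal(names(spec$cells), want) || length(spec$cells) != 6)
    fail("cells", sprintf("must contain exactly one cell_spec per MA x TP pair (%s)",
                          paste(want, collapse = ", ")))
  for (nm in names(spec$cells)) {
    cl <- spec$cells[[nm]]
    if (!inherits(cl, "cell_spec")) fail("cells", sprintf("element '%s' is not a cell_spec", nm))
    for (ev in cl$evoked) {
      unknown <- setdiff(names(ev$channel_weights), spec$channels)
      if (length(unknown))
        fail("cells", sprintf("evoked '%s' in '%s' references unknown channel(s) %s",
                              ev$label, nm, paste(unknown, collapse = ",")))
    }
    for (os in cl$oscillations) {
      if (os$center_freq_hz >= spec$sampling_rate / 2)
        fail("cells", sprintf("oscillation at %g Hz in '%s' exceeds Nyquist", os$center_freq_hz, nm))
    }
  }
  invisible(spec)
}

#' Paper-like default design
#'
#' The packaged reference scenario for one sensory modality: 27 subjects,
#' 38 qualified trials per cell, 200 Hz sampling, epochs from -1.0 to +0.8 s
#' around the second stimulus with the first stimulus at -0.4 s.
#'
#' The visual scenario places N1/N2 deflections and a theta (6 Hz)
#' phase-locked oscillation on occipital channels. In attended cells the
#' violated-prediction condition has a reduced N1, an enhanced N2 and a
#' reduced theta phase concentration; unattended cells have identical
#' components across TP levels, so any TP effect there is spurious. The
#' auditory scenario places P2 deflections and a delta (2.5 Hz) oscillation
#' on frontal channels, with the matched-prediction condition largest when
#' attended. Behavioural distributions reproduce the fast/intermediate/slow
#' reaction-time ordering across NTP/MTP/VTP and the corresponding accuracy
#' gradient.
#'
#' @param modality `"visual"` or `"auditory"`.
#' @param n_subjects,n_trials_per_cell Override the default sizes.
#' @return A [design_spec()].
#' @export
default_design <- function(modality = c("visual", "auditory"),
                           n_subjects = 27, n_trials_per_cell = 38) {
  modality <- match.arg(modality)
  if (modality == "visual") {
    chans <- c("O1", "OZ", "O2")
    w <- setNames(rep(1, 3), chans)
    behav <- list(NTP = behavior_spec(0.999, 0.292, 0.060, 0.08),
                  MTP = behavior_spec(0.982, 0.442, 0.060, 0.08),
                  VTP = behavior_spec(0.912, 0.607, 0.060, 0.08))
    n1_amp <- list(attended = c(NTP = -5, MTP = -5, VTP = -3.5),
                   unattended = c(NTP = -3, MTP = -3, VTP = -3))
    n2_amp <- list(attended = c(NTP = -1, MTP = -1, VTP = -2),
                   unattended = c(NTP = -1, MTP = -1, VTP = -1))
    kap <- list(attended = c(NTP = 1.5, MTP = 1.5, VTP = 0.3),
                unattended = c(NTP = 0.9, MTP = 0.9, VTP = 0.9))
    cells <- list()
    for (ma in c("attended", "unattended")) for (tp in c("NTP", "MTP", "VTP")) {
      cells[[cell_key(ma, tp)]] <- cell_spec(
        evoked = list(
          evoked_component("N1_first", 0.170, "first", 0.020, -3, w,
                           amplitude_jitter_sd_uv = 0.5, latency_jitter_sd_s = 0.005),
          evoked_component("N1_second", 0.155, "second", 0.020, n1_amp[[ma]][[tp]], w,
                           amplitude_jitter_sd_uv = 0.5, latency_jitter_sd_s = 0.005),
          evoked_component("N2_second", 0.250, "second", 0.030, n2_amp[[ma]][[tp]], w,
                           amplitude_jitter_sd_uv = 0.5, latency_jitter_sd_s = 0.005)),
        oscillations = list(
          osc_component(6, kap[[ma]][[tp]], 0, "second", 2, c(0.05, 0.35), w)),
        noise = noise_spec(1, 4),
        behavior = behav[[tp]])
    }
    design_spec(n_subjects = n_subjects, n_trials_per_cell = n_trials_per_cell,
                channels = chans, cells = cells)
  } else {
    chans <- c("F1", "FZ", "F2")
    w <- setNames(rep(1, 3), chans)
    behav <- list(NTP = behavior_spec(0.9996, 0.300, 0.060, 0.08),
                  MTP = behavior_spec(0.9783, 0.435, 0.060, 0.08),
                  VTP = behavior_spec(0.9383, 0.566, 0.060, 0.08))
    p2_amp <- list(attended = c(NTP = 2.5, MTP = 4, VTP = 2.5),
                   unattended = c(NTP = 2, MTP = 2, VTP = 2))
    kap <- list(attended = c(NTP = 0.8, MTP = 1.6, VTP = 0.8),
                unattended = c(NTP = 0.8, MTP = 0.8, VTP = 0.8))
    cells <- list()
    for (ma in c("attended", "unattended")) for (tp in c("NTP", "MTP", "VTP")) {
      cells[[cell_key(ma, tp)]] <- cell_spec(
        evoked = list(
          evoked_component("P2_first", 0.195, "first", 0.025, 2, w,
                           amplitude_jitter_sd_uv = 0.5, latency_jitter_sd_s = 0.005),
          evoked_component("P2_second", 0.180, "second", 0.040, p2_amp[[ma]][[tp]], w,
                           amplitude_jitter_sd_uv = 0.5, latency_jitter_sd_s = 0.005)),
        oscillations = list(
          osc_component(2.5, kap[[ma]][[tp]], 0, "second", 2, c(0.05, 0.45), w)),
        noise = noise_spec(1, 4),
        behavior = behav[[tp]])
    }
    design_spec(n_subjects = n_subjects, n_trials_per_cell = n_trials_per_cell,
                channels = chans, cells = cells)
  }
}

#' Global-null design
#'
#' Every cell is generated from the same distribution (identical evoked
#' component, no oscillation effects, same noise), so any effect reported
#' downstream is a false positive. Used for type-I-error simulations.
#'
#' @param n_subjects,n_trials_per_cell Simulated sizes.
#' @param channels Channel labels (a single channel keeps null simulations cheap).
#' @param noise_sd_uv Noise SD, microvolts.
#' @return A [design_spec()].
#' @export
null_design <- function(n_subjects = 12, n_trials_per_cell = 20,
                        channels = "OZ", noise_sd_uv = 4) {
  w <- setNames(rep(1, length(channels)), channels)
  base_cell <- cell_spec(
    evoked = list(evoked_component("N1_second", 0.155, "second", 0.020, -4, w)),
    noise = noise_spec(1, noise_sd_uv),
    behavior = behavior_spec(0.97, 0.35, 0.06, 0.08))
  cells <- list()
  for (ma in c("attended", "unattended")) for (tp in c("NTP", "MTP", "VTP"))
    cells[[cell_key(ma, tp)]] <- base_cell
  design_spec(n_subjects = n_subjects, n_trials_per_cell = n_trials_per_cell,
              channels = channels, cells = cells)
}

## ---- YAML round-trip --------------------------------------------------

design_to_list <- function(spec) {
  cells <- lapply(spec$cells, function(cl) {
    list(evoked = lapply(cl$evoked, unclass_weights),
         oscillations = lapply(cl$oscillations, unclass_weights),
         noise = unclass(cl$noise),
         behavior = unclass(cl$behavior))
  })
  list(ma_levels = spec$ma_levels, tp_levels = spec$tp_levels,
       n_subjects = spec$n_subjects, n_trials_per_cell = spec$n_trials_per_cell,
       sampling_rate = spec$sampling_rate, epoch_window = spec$epoch_window,
       first_stim_offset_s = spec$first_stim_offset_s,
       channels = as.list(spec$channels), cells = cells)
}

unclass_weights <- function(comp) {
  x <- unclass(comp)
  x$channel_weights <- as.list(x$channel_weights)
  x
}

list_to_component <- function(x, ctor) {
  x$channel_weights <- unlist(x$channel_weights)
  do.call(ctor, x)
}

#' Write / read a design specification as YAML
#'
#' @param spec A [design_spec()].
#' @param path File path.
#' @return `read_design_yaml` returns a [design_spec()].
#' @export
write_design_yaml <- function(spec, path) {
  yaml::write_yaml(design_to_list(spec), path)
  invisible(path)
}

#' @rdname write_design_yaml
#' @export
read_design_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  cells <- lapply(x$cells, function(cl) {
    cell_spec(
      evoked = lapply(cl$evoked, list_to_component, ctor = evoked_component),
      oscillations = lapply(cl$oscillations, list_to_component, ctor = osc_component),
      noise = do.call(noise_spec, cl$noise[c("one_over_f_exponent", "noise_sd_uv")]),
      behavior = do.call(behavior_spec, cl$behavior))
  })
  design_spec(ma_levels = unlist(x$ma_levels), tp_levels = unlist(x$tp_levels),
              n_subjects = x$n_subjects, n_trials_per_cell = x$n_trials_per_cell,
              sampling_rate = x$sampling_rate, epoch_window = unlist(x$epoch_window),
              first_stim_offset_s = x$first_stim_offset_s,
              channels = unlist(x$channels), cells = cells)
}
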