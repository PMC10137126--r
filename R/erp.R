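#' Component-window definition
#'
#' A named ERP component measured as the mean amplitude inside a temporal
#' window over a set of electrodes. Windows are stored relative to the zero
#' point (second-stimulus onset); components locked to the first stimulus
#' carry `locking = "first"` so the matching pre-stimulus baseline is used.
#'
#' @param name Component label, e.g. `"N1_second"`.
#' @param window_s Length-2 numeric `(start_s, end_s)` relative to the zero
#'   point.
#' @param channels Electrode labels averaged for this component.
#' @param modality `"visual"` or `"auditory"`.
#' @param locking `"first"` or `"second"`: which stimulus evokes it.
#' @return A list of class `component_window`.
#' @export
component_window <- function(name, window_s, channels,
                             modality = c("visual", "auditory"),
                             locking = c("second", "first")) {
  modality <- match.arg(modality)
  locking <- match.arg(locking)
  if (window_s[1] >= window_s[2])
    stop("invalid component_window: start must precede end", call. = FALSE)
  structure(list(name = name, window_s = window_s, channels = channels,
                 modality = modality, locking = locking),
            class = "component_window")
}

#' Default component windows
#'
#' The six windows analysed in this design. Visual components are measured
#' at occipital electrodes O1/OZ/O2, auditory at frontal F1/FZ/F2.
#' First-stimulus windows are defined relative to that stimulus
#' (the visual first N1 spans 140-200 ms after the first flash) and
#' converted here to zero-point coordinates using the 400 ms
#' inter-stimulus interval; the auditory first-P2 window is specified in
#' zero-point coordinates directly.
#'
#' @param modality Restrict to one modality, or `"both"`.
#' @return List of [component_window()].
#' @export
default_component_windows <- function(modality = c("both", "visual", "auditory")) {
  modality <- match.arg(modality)
  occ <- c("O1", "OZ", "O2"); fro <- c("F1", "FZ", "F2")
  w <- list(
    component_window("N1_first",  c(-0.260, -0.200), occ, "visual", "first"),
    component_window("N1_second", c(0.120, 0.190),  occ, "visual", "second"),
    component_window("N2_second", c(0.200, 0.300),  occ, "visual", "second"),
    component_window("P2_first",  c(-0.230, -0.180), fro, "auditory", "first"),
    component_window("P2_second", c(0.110, 0.250),  fro, "auditory", "second"))
  if (modality == "both") w
  else Filter(function(cw) cw$modality == modality, w)
}

#' Condition-average waveform
#'
#' Arithmetic mean across the trials of one MA x TP cell, per channel and
#' sample.
#'
#' @param e An [epoch_set()].
#' @param ma,tp Cell labels.
#' @return A list of class `erp_average` with elements `waveform`
#'   (channels x samples matrix), `times`, `channels`, `n_trials`.
#' @export
condition_average <- function(e, ma, tp) {
  idx <- e$trial_info$ma == ma & e$trial_info$tp == tp
  if (!any(idx))
    stop(sprintf("empty cell: no trials for ma='%s', tp='%s'", ma, tp),
         call. = FALSE)
  wf <- colMeans(e$data[idx, , , drop = FALSE])  # channels x samples
  structure(list(waveform = wf, times = e$times, channels = e$channels,
                 sampling_rate = e$sampling_rate, n_trials = sum(idx)),
            class = "erp_average")
}

#' Window-mean amplitude of an averaged waveform
#'
#' Mean over the samples whose times fall in the closed window (both
#' endpoints inclusive, with a quarter-sample guard on boundary ties), then
#' the unweighted mean across the component's channels.
#'
#' @param avg An `erp_average` from [condition_average()].
#' @param cw A [component_window()], or a length-2 numeric window (then
#'   `channels` must be given).
#' @param channels Channel labels when `cw` is a bare window.
#' @return Scalar mean amplitude, microvolts.
#' @export
window_mean_amplitude <- function(avg, cw, channels = NULL) {
  if (inherits(cw, "component_window")) {
    window <- cw$window_s; channels <- cw$channels
  } else window <- cw
  chi <- match(channels, avg$channels)
  if (anyNA(chi))
    stop("unknown channel(s): ", paste(channels[is.na(chi)], collapse = ", "),
         call. = FALSE)
  idx <- window_sample_idx(avg$times, window, avg$sampling_rate)
  mean(avg$waveform[chi, idx, drop = FALSE])
}

#' Per-subject ERP measure table
#'
#' For each subject, cell and component window: baseline-correct the epochs
#' with the baseline matching the component's locking stimulus (100 ms
#' before the first stimulus for first-locked components, 100 ms before the
#' zero point for second-locked), average the cell's trials and take the
#' window-mean amplitude over the component's electrodes.
#'
#' @param epochs Named list of [epoch_set()], one per subject (as from
#'   [generate_epochs()]).
#' @param windows List of [component_window()].
#' @param first_stim_offset_s Onset of the first stimulus, seconds.
#' @return Long-format data frame (a measure table) with columns
#'   `subject, ma, tp, measure, value`.
#' @export
build_erp_measure_table <- function(epochs, windows = default_component_windows(),
                                    first_stim_offset_s = -0.4) {
  baselines <- list(first = first_stim_offset_s + c(-0.1, 0),
                    second = c(-0.1, 0))
  subject <- ma_v <- tp_v <- measure <- character(0); value <- numeric(0)
  for (subj in names(epochs)) {
    e <- epochs[[subj]]
    miss <- setdiff(unique(unlist(lapply(windows, `[[`, "channels"))), e$channels)
    if (length(miss))
      stop("missing channel(s) for component windows: ",
           paste(miss, collapse = ", "), call. = FALSE)
    for (lock in unique(vapply(windows, `[[`, "", "locking"))) {
      eb <- baseline_correct(e, baselines[[lock]])
      avgs <- list()
      for (ma in unique(e$trial_info$ma)) for (tp in unique(e$trial_info$tp))
        avgs[[paste(ma, tp)]] <- condition_average(eb, ma, tp)
      for (cw in Filter(function(x) x$locking == lock, windows)) {
        for (ma in unique(e$trial_info$ma)) for (tp in unique(e$trial_info$tp)) {
          subject <- c(subject, subj); ma_v <- c(ma_v, ma); tp_v <- c(tp_v, tp)
          measure <- c(measure, cw$name)
          value <- c(value, window_mean_amplitude(avgs[[paste(ma, tp)]], cw))
        }
      }
    }
  }
  data.frame(subject = subject, ma = ma_v, tp = tp_v, measure = measure,
             value = value, stringsAsFactors = FALSE)
}
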