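#' Trial-epoched EEG container
#'
#' An `epoch_set` holds one subject's trials as a 3-D array
#' `trials x channels x samples` (microvolts), together with the sampling
#' rate, the index of the zero-point sample (second-stimulus onset) and a
#' per-trial record of condition labels and behaviour. Time stamps are
#' derived from `(sampling_rate, t0_index)` so the grid is uniform by
#' construction.
#'
#' @param data Numeric array `trials x channels x samples`.
#' @param sampling_rate Sampling rate, Hz.
#' @param t0_index 1-based sample index of the zero point.
#' @param channels Ordered channel labels, length `dim(data)[2]`.
#' @param trial_info Data frame with columns `subject`, `ma`, `tp`, `trial`,
#'   `correct` (logical), `rt_s`; one row per trial.
#' @return A list of class `epoch_set` with derived element `times`.
#' @export
epoch_set <- function(data, sampling_rate, t0_index, channels, trial_info) {
  e <- structure(list(data = data, sampling_rate = sampling_rate,
                      t0_index = as.integer(t0_index), channels = channels,
                      trial_info = trial_info),
                 class = "epoch_set")
  e$times <- epoch_times(e)
  validate_epoch_set(e)
  e
}

epoch_times <- function(e) {
  (seq_len(dim(e$data)[3]) - e$t0_index) / e$sampling_rate
}

#' Validate an epoch_set
#'
#' Checks tensor/metadata consistency: channel count, trial_info length,
#' a uniform time grid and the presence of exactly one zero-point sample.
#'
#' @param e An [epoch_set()].
#' @return `e`, invisibly; errors name the failing field.
#' @export
validate_epoch_set <- function(e) {
  fail <- function(field, why) stop(sprintf("invalid epoch_set: '%s' %s", field, why),
                                    call. = FALSE)
  if (!is.array(e$data) || length(dim(e$data)) != 3)
    fail("data", "must be a trials x channels x samples array")
  d <- dim(e$data)
  if (length(e$channels) != d[2])
    fail("channels", sprintf("has %d labels but tensor has %d channels",
                             length(e$channels), d[2]))
  if (!is.data.frame(e$trial_info) || nrow(e$trial_info) != d[1])
    fail("trial_info", sprintf("has %d rows but tensor has %d trials",
                               if (is.data.frame(e$trial_info)) nrow(e$trial_info) else 0L, d[1]))
  need <- c("subject", "ma", "tp", "trial", "correct", "rt_s")
  miss <- setdiff(need, names(e$trial_info))
  if (length(miss)) fail("trial_info", paste("lacks column(s)", paste(miss, collapse = ",")))
  if (length(e$times) != d[3]) fail("times", "length must equal sample count")
  dt <- diff(e$times)
  if (any(dt <= 0) || any(abs(dt - 1 / e$sampling_rate) > 1e-9))
    fail("times", "must increase uniformly at 1/sampling_rate")
  if (sum(abs(e$times) < 0.5 / e$sampling_rate) != 1)
    fail("t0_index", "must place exactly one sample at the zero point")
  invisible(e)
}

#' Number of trials / channels / samples of an epoch_set
#' @param e An [epoch_set()].
#' @return Integer count.
#' @export
n_trials <- function(e) dim(e$data)[1]

#' @rdname n_trials
#' @export
n_samples <- function(e) dim(e$data)[3]

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("epoch_set: %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$sampling_rate))
  cat(sprintf("  time %.3f .. %.3f s (zero point at sample %d)\n",
              x$times[1], x$times[length(x$times)], x$t0_index))
  cat(sprintf("  channels: %s\n", paste(x$channels, collapse = ", ")))
  cells <- table(paste(x$trial_info$ma, x$trial_info$tp, sep = "."))
  cat("  trials per cell:", paste(names(cells), cells, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

EPOCHS_SCHEMA_VERSION <- 1L

#' Write / read an epoch_set to a directory container
#'
#' The container is a directory holding `metadata.json` (schema-versioned
#' shape and geometry), `data.bin` (little-endian 64-bit floats in
#' trial-major order: trial, then channel, then sample) and
#' `trial_info.csv` with the fixed header
#' `subject,ma,tp,trial,correct,rt_s`. The round trip is bit-exact.
#'
#' @param e An [epoch_set()].
#' @param path Directory path (created if needed).
#' @return `read_epochs` returns the reconstructed [epoch_set()].
#' @export
write_epochs <- function(e, path) {
  validate_epoch_set(e)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  d <- dim(e$data)
  meta <- list(schema_version = EPOCHS_SCHEMA_VERSION,
               n_trials = d[1], n_channels = d[2], n_samples = d[3],
               sampling_rate = e$sampling_rate, t0_index = e$t0_index,
               channels = e$channels)
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  con <- file(file.path(path, "data.bin"), "wb")
  on.exit(close(con))
  # sample varies fastest, then channel, then trial
  writeBin(as.vector(aperm(e$data, c(3, 2, 1))), con, size = 8, endian = "little")
  ti <- e$trial_info[, c("subject", "ma", "tp", "trial", "correct", "rt_s")]
  utils::write.csv(ti, file.path(path, "trial_info.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  meta_path <- file.path(path, "metadata.json")
  if (!file.exists(meta_path))
    stop("epoch container format error: missing metadata.json in ", path, call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (f in c("schema_version", "n_trials", "n_channels", "n_samples",
              "sampling_rate", "t0_index", "channels"))
    if (is.null(meta[[f]]))
      stop("epoch container format error: metadata field '", f, "' missing", call. = FALSE)
  if (meta$schema_version != EPOCHS_SCHEMA_VERSION)
    stop(sprintf("epoch container version error: file has schema %s, reader supports %d",
                 meta$schema_version, EPOCHS_SCHEMA_VERSION), call. = FALSE)
  if (length(meta$channels) != meta$n_channels)
    stop(sprintf("epoch container format error: 'channels' lists %d labels but 'n_channels' is %d",
                 length(meta$channels), meta$n_channels), call. = FALSE)
  n <- meta$n_trials * meta$n_channels * meta$n_samples
  con <- file(file.path(path, "data.bin"), "rb")
  raw <- readBin(con, "numeric", n = n + 1, size = 8, endian = "little")
  close(con)
  if (length(raw) != n)
    stop(sprintf("epoch container format error: 'data.bin' holds %d values, metadata implies %d",
                 length(raw), n), call. = FALSE)
  dat <- aperm(array(raw, dim = c(meta$n_samples, meta$n_channels, meta$n_trials)),
               c(3, 2, 1))
  ti <- utils::read.csv(file.path(path, "trial_info.csv"),
                        colClasses = c(subject = "character", ma = "character",
                                       tp = "character", trial = "integer",
                                       correct = "logical", rt_s = "numeric"))
  epoch_set(dat, meta$sampling_rate, meta$t0_index, meta$channels, ti)
}

#' Write / read a behaviour table as CSV
#'
#' Fixed header `subject,ma,tp,trial,correct,rt_s`; the key
#' (subject, ma, tp, trial) is unique.
#'
#' @param bt Data frame of per-trial behaviour.
#' @param path CSV file path.
#' @return `read_behavior_csv` returns the data frame.
#' @export
write_behavior_csv <- function(bt, path) {
  utils::write.csv(bt[, c("subject", "ma", "tp", "trial", "correct", "rt_s")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_behavior_csv
#' @export
read_behavior_csv <- function(path) {
  bt <- utils::read.csv(path, colClasses = c(subject = "character", ma = "character",
                                             tp = "character", trial = "integer",
                                             correct = "logical", rt_s = "numeric"))
  if (anyDuplicated(bt[, c("subject", "ma", "tp", "trial")]))
    stop("behavior table format error: (subject, ma, tp, trial) not unique", call. = FALSE)
  bt
}

#' Select a subset of trials
#'
#' @param e An [epoch_set()].
#' @param idx Integer or logical trial index.
#' @return An [epoch_set()] with the selected trials.
#' @export
subset_trials <- function(e, idx) {
  epoch_set(e$data[idx, , , drop = FALSE], e$sampling_rate, e$t0_index,
            e$channels, e$trial_info[idx, , drop = FALSE])
}

# Sample indices whose times fall in [start, end], endpoints inclusive with a
# quarter-sample guard against floating-point boundary ties.
window_sample_idx <- function(times, window, sampling_rate) {
  eps <- 0.25 / sampling_rate
  idx <- which(times >= window[1] - eps & times <= window[2] + eps)
  if (!length(idx))
    stop(sprintf("window [%g, %g] s contains no samples", window[1], window[2]),
         call. = FALSE)
  idx
}
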