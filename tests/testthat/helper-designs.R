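# Small design builders shared across tests.

all_cell_keys <- function() {
  as.vector(outer(c("attended", "unattended"), c("NTP", "MTP", "VTP"),
                  function(a, b) paste(a, b, sep = ".")))
}

# One identical cell_spec in every cell.
uniform_design <- function(cell, n_subjects = 1, n_trials = 4,
                           channels = "OZ", epoch_window = c(-1, 0.8),
                           sampling_rate = 200) {
  cells <- setNames(rep(list(cell), 6), all_cell_keys())
  design_spec(n_subjects = n_subjects, n_trials_per_cell = n_trials,
              sampling_rate = sampling_rate, epoch_window = epoch_window,
              channels = channels, cells = cells)
}

# Pure single-component designs used by the oracle tests.
evoked_only_design <- function(amplitude = -5, peak = 0.155, width = 0.02,
                               locking = "second", n_trials = 4,
                               noise_sd = 0, channels = "OZ", ...) {
  w <- setNames(rep(1, length(channels)), channels)
  cell <- cell_spec(
    evoked = list(evoked_component("comp", peak, locking, width, amplitude, w)),
    noise = noise_spec(1, noise_sd))
  uniform_design(cell, n_trials = n_trials, channels = channels, ...)
}

osc_only_design <- function(kappa, freq = 6, amplitude = 2,
                            envelope = c(-0.2, 0.4), n_trials = 100,
                            noise_sd = 0, locked_phase = 0, channels = "OZ", ...) {
  w <- setNames(rep(1, length(channels)), channels)
  cell <- cell_spec(
    oscillations = list(osc_component(freq, kappa, locked_phase, "second",
                                      amplitude, envelope, w)),
    noise = noise_spec(1, noise_sd))
  uniform_design(cell, n_trials = n_trials, channels = channels, ...)
}

one_cell <- function(spec, seed = 1, ma = "attended", tp = "NTP",
                     subject = "S01") {
  e <- generate_subject_epochs(spec, subject, seed)
  subset_trials(e, e$trial_info$ma == ma & e$trial_info$tp == tp)
}

# Hand-built epoch_set from a trials x channels x samples array.
toy_epochs <- function(data, sampling_rate = 200, t0_index = NULL,
                       channels = NULL, ma = "attended", tp = "NTP",
                       correct = TRUE, rt_s = 0.3) {
  d <- dim(data)
  if (is.null(t0_index)) t0_index <- d[3] %/% 2 + 1L
  if (is.null(channels)) channels <- sprintf("CH%d", seq_len(d[2]))
  ti <- data.frame(subject = "S01",
                   ma = rep_len(ma, d[1]), tp = rep_len(tp, d[1]),
                   trial = seq_len(d[1]),
                   correct = rep_len(correct, d[1]),
                   rt_s = rep_len(rt_s, d[1]), stringsAsFactors = FALSE)
  epoch_set(data, sampling_rate, t0_index, channels, ti)
}

# Random balanced 2x3 measure table for ANOVA oracle checks.
random_measure_table <- function(n_subjects, seed) {
  set.seed(seed)
  g <- expand.grid(subject = sprintf("S%02d", seq_len(n_subjects)),
                   ma = c("attended", "unattended"),
                   tp = c("NTP", "MTP", "VTP"), stringsAsFactors = FALSE)
  g$value <- rnorm(nrow(g))
  g
}

# Independent rm-ANOVA oracle via stats::aov with Error strata.
aov_oracle_2way <- function(table) {
  df <- data.frame(subject = factor(table$subject), ma = factor(table$ma),
                   tp = factor(table$tp), value = table$value)
  fit <- summary(aov(value ~ ma * tp + Error(subject / (ma * tp)), data = df))
  grab <- function(stratum, term) {
    tab <- fit[[paste0("Error: ", stratum)]][[1]]
    row <- trimws(rownames(tab)) == term
    c(F = tab[row, "F value"], df1 = tab[row, "Df"],
      df2 = tab[!row, "Df"][sum(!row)], p = tab[row, "Pr(>F)"])
  }
  list(ma = grab("subject:ma", "ma"), tp = grab("subject:tp", "tp"),
       inter = grab("subject:ma:tp", "ma:tp"))
}

aov_oracle_1way <- function(table) {
  df <- data.frame(subject = factor(table$subject), tp = factor(table$tp),
                   value = table$value)
  fit <- summary(aov(value ~ tp + Error(subject / tp), data = df))
  tab <- fit[["Error: subject:tp"]][[1]]
  c(F = tab[1, "F value"], p = tab[1, "Pr(>F)"])
}
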