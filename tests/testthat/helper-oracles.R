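# Brute-force reference implementations: naive per-trial loops, independent
# of the package's vectorized code paths.

itc_loop <- function(coeffs) {
  d <- dim(coeffs)
  out <- array(0, dim = d[2:4])
  for (ch in seq_len(d[2])) for (f in seq_len(d[3])) for (t in seq_len(d[4])) {
    acc <- 0 + 0i; n <- 0
    for (i in seq_len(d[1])) {
      z <- coeffs[i, ch, f, t]
      if (Mod(z) > 0) { acc <- acc + z / Mod(z); n <- n + 1 }
    }
    out[ch, f, t] <- if (n > 0) Mod(acc) / n else 0
  }
  out
}

ersp_loop <- function(coeffs, times, valid, baseline, fs) {
  d <- dim(coeffs)
  out <- array(NA_real_, dim = d[2:4])
  bidx <- which(times >= baseline[1] - 0.25 / fs & times <= baseline[2] + 0.25 / fs)
  for (ch in seq_len(d[2])) for (f in seq_len(d[3])) {
    P <- numeric(d[4])
    for (t in seq_len(d[4])) {
      for (i in seq_len(d[1])) P[t] <- P[t] + Mod(coeffs[i, ch, f, t])^2
      P[t] <- P[t] / d[1]
    }
    bok <- bidx[valid[f, bidx]]
    if (!length(bok)) next
    B <- mean(P[bok])
    out[ch, f, ] <- 10 * log10(P / B)
  }
  out
}

unwrap_phase <- function(p) {
  out <- p
  for (i in 2:length(p)) {
    d <- p[i] - p[i - 1]
    out[i] <- out[i - 1] + atan2(sin(d), cos(d))
  }
  out
}
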