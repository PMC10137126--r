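#' Two-way repeated-measures ANOVA on a measure table
#'
#' Balanced within-subject decomposition for a 2 (MA) x 3 (TP) design: the
#' sums of squares for MA, TP and MA x TP are each tested against their own
#' subject-by-effect interaction mean square (univariate approach, no
#' sphericity correction by default, so a 3-level factor over 27 subjects
#' reports df (2, 52)). Effect size is partial eta squared,
#' `SS_effect / (SS_effect + SS_error)`. A degenerate table with zero total
#' variance reports `F = 0, p = 1`.
#'
#' @param table Measure table rows for a single measure: columns
#'   `subject, ma, tp, value` (one row per subject x cell).
#' @param gg Apply the Greenhouse-Geisser sphericity correction to the
#'   p-values of effects with more than 1 numerator df.
#' @return A data frame of class `anova_report` with one row per effect
#'   (`ma`, `tp`, `ma:tp`) and columns
#'   `effect, df1, df2, F, p, peta2, ss_effect, ss_error` (plus `gg_eps, p_gg`
#'   when `gg = TRUE`).
#' @export
rm_anova_2way <- function(table, gg = FALSE) {
  y <- measure_matrix_3way(table)
  S <- dim(y)[1]; A <- dim(y)[2]; B <- dim(y)[3]
  m <- mean(y)
  m_s <- apply(y, 1, mean); m_a <- apply(y, 2, mean); m_b <- apply(y, 3, mean)
  m_ab <- apply(y, c(2, 3), mean)
  m_sa <- apply(y, c(1, 2), mean); m_sb <- apply(y, c(1, 3), mean)
  ss_a  <- B * S * sum((m_a - m)^2)
  ss_b  <- A * S * sum((m_b - m)^2)
  dev_ab <- m_ab - outer(m_a, rep(1, B)) - outer(rep(1, A), m_b) + m
  ss_ab <- S * sum(dev_ab^2)
  dev_sa <- m_sa - outer(m_s, rep(1, A)) - outer(rep(1, S), m_a) + m
  ss_sa <- B * sum(dev_sa^2)
  dev_sb <- m_sb - outer(m_s, rep(1, B)) - outer(rep(1, S), m_b) + m
  ss_sb <- A * sum(dev_sb^2)
  resid <- y
  for (s in seq_len(S)) for (a in seq_len(A)) for (b in seq_len(B))
    resid[s, a, b] <- y[s, a, b] - m_ab[a, b] - m_sa[s, a] - m_sb[s, b] +
      m_a[a] + m_b[b] + m_s[s] - m
  ss_sab <- sum(resid^2)
  eff <- data.frame(
    effect = c("ma", "tp", "ma:tp"),
    df1 = c(A - 1, B - 1, (A - 1) * (B - 1)),
    df2 = c((A - 1) * (S - 1), (B - 1) * (S - 1), (A - 1) * (B - 1) * (S - 1)),
    ss_effect = c(ss_a, ss_b, ss_ab),
    ss_error = c(ss_sa, ss_sb, ss_sab),
    stringsAsFactors = FALSE)
  finish_anova_report(eff, y_for_gg = if (gg) y else NULL)
}

finish_anova_report <- function(eff, y_for_gg = NULL) {
  ms_eff <- eff$ss_effect / eff$df1
  ms_err <- eff$ss_error / eff$df2
  F <- ifelse(ms_err > 0, ms_eff / ms_err, 0)
  p <- ifelse(ms_err > 0, stats::pf(F, eff$df1, eff$df2, lower.tail = FALSE), 1)
  denom <- eff$ss_effect + eff$ss_error
  peta2 <- ifelse(denom > 0, eff$ss_effect / denom, 0)
  out <- cbind(eff[, c("effect", "df1", "df2")],
               data.frame(F = F, p = p, peta2 = peta2),
               eff[, c("ss_effect", "ss_error")])
  if (!is.null(y_for_gg)) {
    out$gg_eps <- NA_real_; out$p_gg <- out$p
    for (r in seq_len(nrow(out))) {
      if (out$df1[r] > 1 && out$effect[r] %in% c("tp", "ma", "ma:tp")) {
        eps <- gg_epsilon(y_for_gg, out$effect[r])
        out$gg_eps[r] <- eps
        out$p_gg[r] <- stats::pf(out$F[r], out$df1[r] * eps, out$df2[r] * eps,
                                 lower.tail = FALSE)
      }
    }
  }
  class(out) <- c("anova_report", "data.frame")
  out
}

# Greenhouse-Geisser epsilon from the covariance of the relevant
# within-subject contrast scores.
gg_epsilon <- function(y, effect) {
  S <- dim(y)[1]; A <- dim(y)[2]; B <- dim(y)[3]
  scores <- switch(effect,
    tp = apply(y, c(1, 3), mean),
    ma = apply(y, c(1, 2), mean),
    "ma:tp" = {
      d <- y[, 1, , drop = TRUE] - y[, 2, , drop = TRUE]
      matrix(d, nrow = S)
    })
  k <- ncol(scores)
  if (k < 2) return(1)
  V <- stats::cov(scores)
  C <- diag(k) - 1 / k
  M <- C %*% V %*% C
  sum(diag(M))^2 / ((k - 1) * sum(M^2))
}

measure_matrix_3way <- function(table) {
  need <- c("subject", "ma", "tp", "value")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("measure table lacks column(s) ",
                         paste(miss, collapse = ", "), call. = FALSE)
  subjects <- unique(table$subject)
  mas <- level_order(table$ma, c("attended", "unattended"))
  tps <- level_order(table$tp, c("NTP", "MTP", "VTP"))
  y <- array(NA_real_, dim = c(length(subjects), length(mas), length(tps)),
             dimnames = list(subjects, mas, tps))
  for (r in seq_len(nrow(table)))
    y[table$subject[r], table$ma[r], table$tp[r]] <- table$value[r]
  if (anyNA(y)) {
    bad <- which(is.na(y), arr.ind = TRUE)[1, ]
    stop(sprintf("incomplete design: subject '%s' lacks cell %s.%s",
                 subjects[bad[1]], mas[bad[2]], tps[bad[3]]), call. = FALSE)
  }
  y
}

level_order <- function(x, preferred) {
  lv <- unique(x)
  c(intersect(preferred, lv), setdiff(lv, preferred))
}

#' One-way repeated-measures ANOVA of TP within one MA level
#'
#' The simple effect of timing prediction at a single attention level:
#' a one-way within-subject ANOVA across the TP levels of the rows with
#' `ma == within_ma_level`. Computable unconditionally; under the gated
#' scheme it is reported only when the MA x TP interaction is significant.
#'
#' @param table Measure table (`subject, ma, tp, value`).
#' @param within_ma_level MA level at which to test.
#' @return An `anova_report` with a single `tp` row.
#' @export
simple_effects_tp <- function(table, within_ma_level) {
  sub <- table[table$ma == within_ma_level, , drop = FALSE]
  if (!nrow(sub))
    stop(sprintf("no rows at ma level '%s'", within_ma_level), call. = FALSE)
  tps <- level_order(sub$tp, c("NTP", "MTP", "VTP"))
  if (length(tps) < 2)
    stop("simple effect needs at least 2 TP levels", call. = FALSE)
  subjects <- unique(sub$subject)
  y <- matrix(NA_real_, length(subjects), length(tps),
              dimnames = list(subjects, tps))
  for (r in seq_len(nrow(sub))) y[sub$subject[r], sub$tp[r]] <- sub$value[r]
  if (anyNA(y)) {
    bad <- which(is.na(y), arr.ind = TRUE)[1, ]
    stop(sprintf("incomplete design: subject '%s' lacks cell %s.%s",
                 subjects[bad[1]], within_ma_level, tps[bad[2]]), call. = FALSE)
  }
  S <- nrow(y); B <- ncol(y)
  m <- mean(y); m_s <- rowMeans(y); m_b <- colMeans(y)
  ss_b <- S * sum((m_b - m)^2)
  ss_err <- sum((y - outer(m_s, rep(1, B)) - outer(rep(1, S), m_b) + m)^2)
  eff <- data.frame(effect = "tp", df1 = B - 1, df2 = (B - 1) * (S - 1),
                    ss_effect = ss_b, ss_error = ss_err,
                    stringsAsFactors = FALSE)
  finish_anova_report(eff)
}

#' Bonferroni-corrected pairwise paired contrasts
#'
#' Paired t-tests between every pair of factor levels;
#' `p_adj = min(1, p * m)` with `m` the number of pairs within the family
#' (3 for the TP factor). Zero-variance differences make t undefined and are
#' reported as `p = 1` by convention so batch runs stay total.
#'
#' @param table Measure table rows (`subject, value` plus the factor column).
#' @param factor_col Column holding the factor (default `"tp"`).
#' @return Data frame with one row per pair: `level1, level2, mean_diff, t,
#'   df, p, p_adj`.
#' @export
pairwise_bonferroni <- function(table, factor_col = "tp") {
  lv <- level_order(table[[factor_col]], c("NTP", "MTP", "VTP"))
  if (length(lv) < 2) stop("need at least 2 levels for pairwise contrasts",
                           call. = FALSE)
  pairs <- utils::combn(lv, 2)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(j) {
    a <- table[table[[factor_col]] == pairs[1, j], ]
    b <- table[table[[factor_col]] == pairs[2, j], ]
    b <- b[match(a$subject, b$subject), ]
    if (anyNA(b$value) || nrow(a) != nrow(b))
      stop("unpaired data: subjects differ between levels ",
           pairs[1, j], " and ", pairs[2, j], call. = FALSE)
    d <- a$value - b$value
    n <- length(d)
    if (stats::sd(d) == 0) {
      data.frame(level1 = pairs[1, j], level2 = pairs[2, j],
                 mean_diff = mean(d), t = NA_real_, df = n - 1, p = 1,
                 stringsAsFactors = FALSE)
    } else {
      tt <- stats::t.test(a$value, b$value, paired = TRUE)
      data.frame(level1 = pairs[1, j], level2 = pairs[2, j],
                 mean_diff = mean(d), t = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(1, out$p * m)
  out
}

#' The gated interaction / simple-effects decision scheme
#'
#' For each measure in the table, runs the 2 x 3 repeated-measures ANOVA and
#' branches at `alpha`: if the MA x TP interaction is significant, the
#' simple effect of TP is tested within each MA level and, where that simple
#' effect is itself significant, Bonferroni-corrected pairwise TP contrasts
#' are reported for that level. If the interaction is not significant, the
#' two main effects are tested instead and a significant TP main effect is
#' followed by its pairwise contrasts.
#'
#' @param table Measure table (`subject, ma, tp, measure, value`); a table
#'   without a `measure` column is treated as a single unnamed measure.
#' @param alpha Gate level (default 0.05).
#' @return A list of class `gated_report`, one element per measure:
#'   `anova` (full 2-way report), `branch` (`"simple_effects"` or
#'   `"main_effects"`), `simple` (per-MA-level one-way reports),
#'   `pairwise` (named list of contrast tables that passed the gate) and
#'   `alpha`.
#' @export
run_gated_analysis <- function(table, alpha = 0.05) {
  if (!"measure" %in% names(table)) table$measure <- "value"
  out <- list()
  for (ms in unique(table$measure)) {
    tab <- table[table$measure == ms, , drop = FALSE]
    full <- rm_anova_2way(tab)
    inter_p <- full$p[full$effect == "ma:tp"]
    rep <- list(measure = ms, anova = full, alpha = alpha,
                simple = list(), pairwise = list())
    if (inter_p < alpha) {
      rep$branch <- "simple_effects"
      for (ma in unique(tab$ma)) {
        se <- simple_effects_tp(tab, ma)
        rep$simple[[ma]] <- se
        if (se$p[1] < alpha)
          rep$pairwise[[ma]] <- pairwise_bonferroni(tab[tab$ma == ma, ], "tp")
      }
    } else {
      rep$branch <- "main_effects"
      tp_p <- full$p[full$effect == "tp"]
      if (tp_p < alpha)
        rep$pairwise[["tp_main"]] <- pairwise_bonferroni(
          stats::aggregate(value ~ subject + tp, tab, mean), "tp")
    }
    class(rep) <- "gated_measure_report"
    out[[ms]] <- rep
  }
  class(out) <- "gated_report"
  out
}

#' Significant final pairwise claims of a gated report
#'
#' @param report A `gated_report` from [run_gated_analysis()].
#' @param alpha Significance level for the adjusted p-values.
#' @return Data frame of significant contrasts (possibly empty) with columns
#'   `measure, family, level1, level2, p_adj`.
#' @export
significant_pairs <- function(report, alpha = 0.05) {
  rows <- list(); i <- 0L
  for (rep in report) {
    for (fam in names(rep$pairwise)) {
      pw <- rep$pairwise[[fam]]
      sig <- pw[pw$p_adj < alpha, , drop = FALSE]
      if (nrow(sig)) {
        i <- i + 1L
        rows[[i]] <- data.frame(measure = rep$measure, family = fam,
                                level1 = sig$level1, level2 = sig$level2,
                                p_adj = sig$p_adj, stringsAsFactors = FALSE)
      }
    }
  }
  if (i == 0) data.frame(measure = character(), family = character(),
                         level1 = character(), level2 = character(),
                         p_adj = numeric(), stringsAsFactors = FALSE)
  else do.call(rbind, rows)
}

#' Behavioural statistics
#'
#' Per subject and cell, the mean reaction time over qualified trials
#' (correct and RT at or above the anticipation floor) and the accuracy rate
#' (qualified trials / total trials). Within each MA level, a one-way
#' repeated-measures ANOVA compares the three TP conditions on each
#' behavioural measure, followed by Bonferroni pairwise contrasts when the
#' ANOVA is significant. A measure with zero variance in a level (e.g.
#' accuracy identically 1) is reported as non-testable.
#'
#' @param bt Behaviour table (`subject, ma, tp, trial, correct, rt_s`).
#' @param anticipation_floor_s Anticipation threshold, seconds.
#' @param alpha Significance level for following up with contrasts.
#' @return A list of class `behavior_report`: `summary` (per subject x cell
#'   RT mean and accuracy) and, per MA level and measure, the ANOVA report,
#'   contrasts and a `testable` flag.
#' @export
behavior_stats <- function(bt, anticipation_floor_s = 0.080, alpha = 0.05) {
  qual <- bt$correct & bt$rt_s >= anticipation_floor_s
  key <- interaction(bt$subject, bt$ma, bt$tp, drop = TRUE)
  if (any(tapply(qual, key, sum) == 0))
    stop("behavior_stats: a subject x cell has no qualified trials", call. = FALSE)
  agg <- do.call(rbind, lapply(split(seq_len(nrow(bt)), key), function(ix) {
    data.frame(subject = bt$subject[ix[1]], ma = bt$ma[ix[1]], tp = bt$tp[ix[1]],
               rt_mean_s = mean(bt$rt_s[ix][qual[ix]]),
               accuracy = mean(qual[ix]), stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  tests <- list()
  for (ma in unique(agg$ma)) for (msr in c("rt_mean_s", "accuracy")) {
    tab <- data.frame(subject = agg$subject[agg$ma == ma],
                      ma = ma, tp = agg$tp[agg$ma == ma],
                      value = agg[[msr]][agg$ma == ma], stringsAsFactors = FALSE)
    testable <- stats::sd(tab$value) > 0
    res <- list(testable = testable)
    if (testable) {
      res$anova <- simple_effects_tp(tab, ma)
      if (res$anova$p[1] < alpha) res$pairwise <- pairwise_bonferroni(tab, "tp")
    }
    tests[[paste(ma, msr, sep = ".")]] <- res
  }
  structure(list(summary = agg, tests = tests,
                 anticipation_floor_s = anticipation_floor_s),
            class = "behavior_report")
}

#' Paired comparison of two modalities' behaviour
#'
#' Paired t-tests between two behaviour tables (e.g. the visual and the
#' auditory task) on per-subject mean reaction time and accuracy, computed
#' over qualified trials of the attended conditions.
#'
#' @param bt1,bt2 Behaviour tables for the two tasks.
#' @param ma_level Attention level to compare (default `"attended"`).
#' @param anticipation_floor_s Anticipation threshold, seconds.
#' @return Data frame with one row per measure: `measure, mean1, mean2, t,
#'   df, p`.
#' @export
compare_modalities <- function(bt1, bt2, ma_level = "attended",
                               anticipation_floor_s = 0.080) {
  per_subject <- function(bt) {
    bt <- bt[bt$ma == ma_level, ]
    qual <- bt$correct & bt$rt_s >= anticipation_floor_s
    data.frame(
      subject = sort(unique(bt$subject)),
      rt = tapply(bt$rt_s[qual], bt$subject[qual], mean)[sort(unique(bt$subject))],
      acc = tapply(qual, bt$subject, mean)[sort(unique(bt$subject))])
  }
  a <- per_subject(bt1); b <- per_subject(bt2)
  if (!identical(a$subject, b$subject))
    stop("compare_modalities: tables have different subjects", call. = FALSE)
  row_for <- function(x, y, name) {
    if (stats::sd(x - y) == 0)
      return(data.frame(measure = name, mean1 = mean(x), mean2 = mean(y),
                        t = NA_real_, df = length(x) - 1, p = 1))
    tt <- stats::t.test(x, y, paired = TRUE)
    data.frame(measure = name, mean1 = mean(x), mean2 = mean(y),
               t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
  }
  rbind(row_for(a$rt, b$rt, "rt_mean_s"), row_for(a$acc, b$acc, "accuracy"))
}

#' @export
print.anova_report <- function(x, ...) {
  for (r in seq_len(nrow(x))) {
    cat(sprintf("%-6s F(%d,%d) = %.3f, p = %s, petasq = %.3f\n",
                x$effect[r], x$df1[r], x$df2[r], x$F[r], format_p(x$p[r]),
                x$peta2[r]))
  }
  invisible(x)
}

format_p <- function(p) if (p < 0.001) "< 0.001" else sprintf("%.3f", p)

#' @export
print.gated_report <- function(x, ...) {
  for (rep in x) {
    cat(sprintf("== %s (branch: %s) ==\n", rep$measure, rep$branch))
    print(rep$anova)
    for (ma in names(rep$simple)) {
      cat(sprintf("  simple effect of TP @ %s: ", ma))
      se <- rep$simple[[ma]]
      cat(sprintf("F(%d,%d) = %.3f, p = %s\n", se$df1[1], se$df2[1],
                  se$F[1], format_p(se$p[1])))
    }
    for (fam in names(rep$pairwise)) {
      pw <- rep$pairwise[[fam]]
      for (r in seq_len(nrow(pw)))
        cat(sprintf("  %s: %s vs %s p_adj = %s\n", fam, pw$level1[r],
                    pw$level2[r], format_p(pw$p_adj[r])))
    }
  }
  invisible(x)
}
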