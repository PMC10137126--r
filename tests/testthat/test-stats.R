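test_that("two-way rm-ANOVA reports the design's df structure", {
  tab <- random_measure_table(27, seed = 1)
  rep <- rm_anova_2way(tab)
  expect_equal(rep$df1[rep$effect == "ma"], 1)
  expect_equal(rep$df2[rep$effect == "ma"], 26)
  expect_equal(rep$df1[rep$effect == "tp"], 2)
  expect_equal(rep$df2[rep$effect == "tp"], 52)
  expect_equal(rep$df1[rep$effect == "ma:tp"], 2)
  expect_equal(rep$df2[rep$effect == "ma:tp"], 52)
  se <- simple_effects_tp(tab, "attended")
  expect_equal(c(se$df1, se$df2), c(2, 52))
})

test_that("F statistics match the aov Error-strata oracle on random tables", {
  for (seed in 1:10) {
    tab <- random_measure_table(sample(4:8, 1), seed = 100 + seed)
    rep <- rm_anova_2way(tab)
    orc <- aov_oracle_2way(tab)
    expect_equal(rep$F[rep$effect == "ma"], unname(orc$ma["F"]), tolerance = 1e-8)
    expect_equal(rep$F[rep$effect == "tp"], unname(orc$tp["F"]), tolerance = 1e-8)
    expect_equal(rep$F[rep$effect == "ma:tp"], unname(orc$inter["F"]),
                 tolerance = 1e-8)
    expect_equal(rep$p[rep$effect == "ma:tp"], unname(orc$inter["p"]),
                 tolerance = 1e-8)
    se <- simple_effects_tp(tab, "unattended")
    orc1 <- aov_oracle_1way(tab[tab$ma == "unattended", ])
    expect_equal(se$F[1], unname(orc1["F"]), tolerance = 1e-8)
    expect_equal(se$p[1], unname(orc1["p"]), tolerance = 1e-8)
  }
})

test_that("degenerate all-identical table reports F = 0, p = 1", {
  tab <- random_measure_table(5, seed = 3)
  tab$value <- 7
  rep <- rm_anova_2way(tab)
  expect_true(all(rep$F == 0))
  expect_true(all(rep$p == 1))
  expect_true(all(rep$peta2 == 0))
})

test_that("partial eta squared is within [0,1] and affine-invariant", {
  tab <- random_measure_table(8, seed = 4)
  rep <- rm_anova_2way(tab)
  expect_true(all(rep$peta2 >= 0 & rep$peta2 <= 1))
  tab2 <- tab; tab2$value <- 3.7 * tab$value - 11
  rep2 <- rm_anova_2way(tab2)
  expect_equal(rep2$peta2, rep$peta2, tolerance = 1e-10)
  expect_equal(rep2$F, rep$F, tolerance = 1e-10)
})

test_that("adding a constant to one subject's cells changes no within-subject F", {
  tab <- random_measure_table(6, seed = 5)
  tab2 <- tab
  tab2$value[tab2$subject == "S03"] <- tab2$value[tab2$subject == "S03"] + 100
  expect_equal(rm_anova_2way(tab2)$F, rm_anova_2way(tab)$F, tolerance = 1e-8)
})

test_that("incomplete designs and degenerate factors raise named errors", {
  tab <- random_measure_table(4, seed = 6)
  expect_error(rm_anova_2way(tab[-1, ]), "incomplete design.*S01",
               perl = TRUE)
  expect_error(simple_effects_tp(tab[tab$tp == "NTP", ], "attended"),
               "2 TP levels")
})

test_that("Bonferroni pairwise contrasts follow the textbook paired t", {
  # closed-form oracle: t = mean(d) / (sd(d)/sqrt(n))
  set.seed(7)
  tab <- data.frame(subject = rep(sprintf("S%d", 1:9), 3),
                    tp = rep(c("NTP", "MTP", "VTP"), each = 9),
                    value = rnorm(27))
  pw <- pairwise_bonferroni(tab, "tp")
  expect_equal(nrow(pw), 3)
  for (r in 1:3) {
    a <- tab$value[tab$tp == pw$level1[r]]
    b <- tab$value[tab$tp == pw$level2[r]]
    d <- a - b
    t_ref <- mean(d) / (sd(d) / sqrt(9))
    p_ref <- 2 * pt(-abs(t_ref), 8)
    expect_equal(pw$t[r], t_ref, tolerance = 1e-10)
    expect_equal(pw$p[r], p_ref, tolerance = 1e-10)
    expect_equal(pw$p_adj[r], min(1, p_ref * 3), tolerance = 1e-10)
  }
})

test_that("pairwise contrasts: 0.02 raw becomes 0.06 adjusted; ties give p = 1", {
  # construct a pair whose raw p is exactly scaled by m = 3
  set.seed(8)
  tab <- data.frame(subject = rep(sprintf("S%d", 1:6), 3),
                    tp = rep(c("NTP", "MTP", "VTP"), each = 6),
                    value = rnorm(18))
  pw <- pairwise_bonferroni(tab, "tp")
  expect_equal(pw$p_adj, pmin(1, pw$p * 3), tolerance = 1e-12)

  tie <- tab
  tie$value <- rep(1:6, 3)  # identical across levels
  pw2 <- pairwise_bonferroni(tie, "tp")
  expect_true(all(pw2$p == 1))
  expect_true(all(is.na(pw2$t)))
})

test_that("the gated scheme takes the right branch on programmed structures", {
  # interaction-only structure: TP effect at one MA level, flat at the other
  mk <- function(f) {
    g <- random_measure_table(10, seed = 9)
    g$value <- rnorm(nrow(g), sd = 0.3) + f(g)
    g
  }
  set.seed(10)
  inter <- mk(function(g) ifelse(g$ma == "attended",
                                 ifelse(g$tp == "VTP", -2, 0), 0))
  rep <- run_gated_analysis(inter)[[1]]
  expect_equal(rep$branch, "simple_effects")
  expect_lt(rep$simple$attended$p[1], 0.05)
  expect_gt(rep$simple$unattended$p[1], 0.05)
  expect_true("attended" %in% names(rep$pairwise))
  expect_false("unattended" %in% names(rep$pairwise))

  main <- mk(function(g) ifelse(g$ma == "attended", 3, 0))
  rep2 <- run_gated_analysis(main)[[1]]
  expect_equal(rep2$branch, "main_effects")
  expect_lt(rep2$anova$p[rep2$anova$effect == "ma"], 0.05)
})

test_that("behavioral statistics recover the programmed RT ordering", {
  spec <- default_design("visual", n_subjects = 27)
  bt <- generate_behavior_table(spec, seed = 11)
  rep <- behavior_stats(bt)
  cm <- tapply(rep$summary$rt_mean_s[rep$summary$ma == "attended"],
               rep$summary$tp[rep$summary$ma == "attended"], mean)
  expect_true(cm["NTP"] < cm["MTP"] && cm["MTP"] < cm["VTP"])
  rt_test <- rep$tests[["attended.rt_mean_s"]]
  expect_true(rt_test$testable)
  expect_lt(rt_test$anova$p[1], 0.001)
  expect_true(all(rt_test$pairwise$p_adj < 0.001))
  acc_test <- rep$tests[["attended.accuracy"]]
  expect_lt(acc_test$anova$p[1], 0.05)
})

test_that("all-equal behavior is reported non-testable, not an error", {
  w <- c(OZ = 1)
  cell <- cell_spec(noise = noise_spec(1, 0),
                    behavior = behavior_spec(1.0, 0.4, 0, 0.08))
  spec <- uniform_design(cell, n_subjects = 3, n_trials = 5)
  bt <- generate_behavior_table(spec, seed = 12)
  rep <- behavior_stats(bt)
  expect_false(rep$tests[["attended.accuracy"]]$testable)
  expect_false(rep$tests[["attended.rt_mean_s"]]$testable)
})

test_that("modality comparison pairs subjects and handles ties", {
  sv <- default_design("visual", n_subjects = 8)
  sa <- default_design("auditory", n_subjects = 8)
  btv <- generate_behavior_table(sv, seed = 13)
  bta <- generate_behavior_table(sa, seed = 14)
  cmp <- compare_modalities(btv, bta)
  expect_equal(cmp$measure, c("rt_mean_s", "accuracy"))
  expect_true(all(cmp$p >= 0 & cmp$p <= 1))
  cmp2 <- compare_modalities(btv, btv)
  expect_true(all(cmp2$p == 1))  # identical tables -> zero-variance convention
})

test_that("Greenhouse-Geisser option shrinks df-sensitive p-values sanely", {
  tab <- random_measure_table(9, seed = 15)
  # inject a TP effect so F > 1 (where shrinking df must inflate p)
  tab$value <- tab$value + ifelse(tab$tp == "VTP", 2, 0)
  rep <- rm_anova_2way(tab, gg = TRUE)
  eps <- rep$gg_eps[rep$effect == "tp"]
  expect_true(eps > 0.5 && eps <= 1)  # 1/(k-1) lower bound for k = 3
  expect_gt(rep$F[rep$effect == "tp"], 1)
  expect_gte(rep$p_gg[rep$effect == "tp"], rep$p[rep$effect == "tp"])
  expect_true(all(is.na(rep$gg_eps[rep$effect == "ma"])) ||
                rep$gg_eps[rep$effect == "ma"] == 1)
})
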