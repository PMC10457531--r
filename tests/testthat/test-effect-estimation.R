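# ATE, Cohen's d, reliable change, univariate moderation, percentile bands.

test_that("cohens_d is the ratio with CI bounds scaled identically", {
  expect_equal(cohens_d(0, c(-1, 1), 5)$d, 0)
  es <- cohens_d(-2.165, NULL, 5)
  expect_equal(es$d, -0.433)
  es2 <- cohens_d(-2, c(-3, -1), 5)
  expect_equal(c(es2$ci_low, es2$ci_high), c(-0.6, -0.2))
  expect_error(cohens_d(1, NULL, 0), "positive")
  expect_error(cohens_d(1, NULL, -2), "positive")
})

test_that("ATE is location invariant and pools cleanly", {
  d <- generate_trial_pair(synthetic_config(seed = 67, missing_rate = 0))
  a1 <- estimate_ate(d)
  d2 <- d
  d2$phq9_post <- d2$phq9_post + 7
  a2 <- estimate_ate(d2)
  expect_equal(a1$pooled$estimate, a2$pooled$estimate, tolerance = 1e-5)
  expect_equal(a1$effect_size$d, a2$effect_size$d, tolerance = 1e-5)
  expect_equal(a1$effect_size$d,
               a1$pooled$estimate / sd(d$phq9_baseline))
})

test_that("null ATE is unbiased with approximately nominal CI coverage", {
  S <- 150
  dd <- numeric(S); cover <- logical(S)
  for (i in seq_len(S)) {
    a <- estimate_ate(generate_trial_pair(null_config(i)))
    dd[i] <- a$effect_size$d
    cover[i] <- a$effect_size$ci_low <= 0 && a$effect_size$ci_high >= 0
  }
  expect_lt(abs(mean(dd)), 2.5 * sd(dd) / sqrt(S))
  # the Wishart prior keeps tau2 > 0, so with no true heterogeneity the
  # interval is conservative (coverage at or above nominal, never below)
  expect_gte(mean(cover), 0.95)
})

test_that("reliable change reproduces the published index arithmetic", {
  cfg <- rci_config(reliability = 0.84, sd_baseline = 4.55)
  n <- 8
  tab <- data.frame(
    trial = factor(rep("trial_A", n), levels = c("trial_A", "trial_B")),
    arm = factor(rep(c("control", "intervention"), each = n / 2),
                 levels = c("control", "intervention")),
    phq9_baseline = rep(15, n),
    phq9_post = c(15, 15, 15, 15, 9, 9, 10, 10))
  rc <- reliable_change(tab, cfg)
  expect_equal(rc$se_diff, 4.55 * sqrt(2 * (1 - 0.84)), tolerance = 1e-12)
  expect_equal(round(rc$se_diff, 3), 2.574)
  expect_equal(round(rc$threshold, 3), 5.045)
  # delta -6 is reliable improvement, delta -5 is not
  expect_equal(rc$by_arm$improved[rc$by_arm$arm == "intervention"], 2L)
  expect_equal(rc$by_arm$improved[rc$by_arm$arm == "control"], 0L)
  # no change -> nobody improves
  tab0 <- tab; tab0$phq9_post <- tab0$phq9_baseline
  rc0 <- reliable_change(tab0, cfg)
  expect_true(all(rc0$by_arm$improved == 0))
  expect_true(all(rc0$rc == 0))
  # shift invariance: adding a constant to baseline and post changes nothing
  tab1 <- tab; tab1$phq9_baseline <- tab1$phq9_baseline + 4
  tab1$phq9_post <- tab1$phq9_post + 4
  expect_equal(reliable_change(tab1, cfg)$by_arm, rc$by_arm)
  expect_error(rci_config(reliability = 1.2), "reliability")
})

test_that("published improvement counts round to the printed rates", {
  expect_equal(proportion_percent(62, 253, 0), 25)
  expect_equal(proportion_percent(28, 251, 0), 11)
})

test_that("univariate moderation recovers a planted binary interaction", {
  S <- 100
  beta <- vapply(seq_len(S), function(i) {
    cfg <- synthetic_config(
      true_subgroup_rules = list(
        list(when = "prev_pain_medication == 'yes'", d = -1.945 / 4.55),
        list(when = "prev_pain_medication == 'no'", d = 0)),
      tau2_slope = 0, missing_rate = 0, seed = i)
    d <- generate_trial_pair(cfg)
    univariate_moderation(d, "prev_pain_medication")$beta_interaction
  }, numeric(1))
  expect_lt(abs(mean(beta) - (-1.945)), 0.2)
})

test_that("degenerate moderators are rejected", {
  d <- generate_trial_pair(synthetic_config(seed = 71))
  d$flat <- 1
  expect_error(univariate_moderation(d, "flat"), "constant")
  d$treatcopy <- as.numeric(d$arm == "intervention")
  expect_error(univariate_moderation(d, "treatcopy"), "collinear")
  expect_error(univariate_moderation(d, "education"), "more than 2 levels")
})

test_that("binary moderators come with per-level subgroup effect sizes", {
  d <- generate_trial_pair(synthetic_config(seed = 73, missing_rate = 0))
  m <- univariate_moderation(d, "prev_pain_medication")
  expect_named(m$subgroup_effects, c("no", "yes"))
  expect_s3_class(m$subgroup_effects$yes, "effect_size")
})

test_that("mixed and CR2 engines agree when there is no trial heterogeneity", {
  dif <- vapply(1:10, function(i) {
    d <- generate_trial_pair(null_config(i))
    abs(univariate_moderation(d, "pseq", engine = "mpl_lmm")$beta_interaction -
          univariate_moderation(d, "pseq", engine = "ols_cr2")$beta_interaction)
  }, numeric(1))
  expect_lt(mean(dif), 0.05)
})

test_that("percentile bands split exact uniform data evenly and average correctly", {
  n <- 100
  tab <- data.frame(
    trial = factor(rep(c("trial_A", "trial_B"), n / 2)),
    arm = factor(rep(c("control", "intervention"), each = n / 2),
                 levels = c("control", "intervention")),
    phq9_baseline = rep(10, n),
    phq9_post = rep(c(8, 12), n / 2),
    grad = seq_len(n))
  pt <- percentile_change_analysis(tab, "grad")
  counts <- tapply(pt$bands$n, pt$bands$band, sum)
  expect_true(all(counts == 20))
  # hand-computable band means on a tiny set
  small <- data.frame(
    trial = factor(rep("trial_A", 10)),
    arm = factor(rep("control", 10), levels = c("control", "intervention")),
    phq9_baseline = rep(10, 10),
    phq9_post = 10 + c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10),
    grad = 1:10)
  ps <- percentile_change_analysis(small, "grad")
  first <- ps$bands[ps$bands$band == "<20th", ]
  expect_equal(first$mean, mean(c(1, 2)))
  expect_error(percentile_change_analysis(tab, "phq9_baseline"),
               "too few distinct")
})

test_that("a planted effect gradient shows monotone band differences", {
  S <- 40
  mono <- vapply(seq_len(S), function(i) {
    cfg <- synthetic_config(n_per_trial = c(1000, 1000),
      true_subgroup_rules = list(
        list(when = "pseq <= 25", d = -1.2),
        list(when = "pseq > 25 & pseq <= 32", d = -0.8),
        list(when = "pseq > 32 & pseq <= 39", d = -0.4),
        list(when = "pseq > 39 & pseq <= 46", d = 0),
        list(when = "pseq > 46", d = 0.4)),
      tau2_intercept = 0, tau2_slope = 0, missing_rate = 0, seed = i)
    d <- generate_trial_pair(cfg)
    b <- percentile_change_analysis(d, "pseq")$bands
    diffs <- sapply(split(b, b$band), function(s)
      s$mean[s$arm == "intervention"] - s$mean[s$arm == "control"])
    all(diff(diffs) > 0)
  }, logical(1))
  expect_gte(mean(mono), 0.9)
})
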