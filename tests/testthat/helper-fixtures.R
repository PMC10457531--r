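# Shared fixture constructors. All data are generated in code at test time.

# Null generator: no treatment effect, no heterogeneity; optionally also no
# prognostic baseline slope (a "full" null where the outcome is independent
# of every moderator, the correct null for instability tests and trees whose
# node model has no baseline adjustment).
null_config <- function(seed, n = 504, full = FALSE, ...) {
  synthetic_config(
    n_per_trial = c(n / 2, n / 2),
    true_subgroup_rules = list(list(when = "TRUE", d = 0)),
    slope_baseline = if (full) 0 else 0.5,
    tau2_intercept = 0, tau2_slope = 0, missing_rate = 0, seed = seed, ...)
}

# Uniform planted treatment effect (no subgroup structure).
uniform_config <- function(seed, d, n = 504, ...) {
  synthetic_config(
    n_per_trial = c(n / 2, n / 2),
    true_subgroup_rules = list(list(when = "TRUE", d = d)),
    tau2_slope = 0, missing_rate = 0, seed = seed, ...)
}

# Planted two-split tree: d = -1.31 on {phq9 > 10 & pseq <= 38}, +0.24
# elsewhere (the two node effects of the published moderate-severity split).
two_split_config <- function(seed) {
  synthetic_config(
    true_subgroup_rules = list(
      list(when = "phq9_baseline > 10 & pseq <= 38", d = -1.31),
      list(when = "phq9_baseline <= 10 | pseq > 38", d = 0.24)),
    tau2_intercept = 0, tau2_slope = 0, missing_rate = 0, seed = seed)
}

# Deterministic hand-built participant table for closed-form checks.
hand_table <- function(n = 12) {
  data.frame(
    id = sprintf("H%02d", seq_len(n)),
    trial = factor(rep(c("trial_A", "trial_B"), length.out = n),
                   levels = c("trial_A", "trial_B", "external")),
    arm = factor(rep(c("control", "intervention"), each = n / 2),
                 levels = c("control", "intervention")),
    phq9_baseline = rep(c(6, 8, 10, 12, 14, 16), length.out = n),
    phq9_post = rep(c(5, 9, 8, 13, 11, 17), length.out = n),
    pseq = rep(c(20, 30, 40, 50, 25, 35), length.out = n),
    stringsAsFactors = FALSE)
}
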