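# Synthetic two-trial individual-participant data with planted treatment-effect
# heterogeneity. The generator emulates the study conditions of the pooled
# trials: N = 504 across two trials with a 253/251 arm split, baseline PHQ-9
# mean 10.06 (SD 4.55), subgroup-specific standardized effects following the
# published decision-tree structure, between-trial heterogeneity of the
# treatment effect, and MAR dropout of the post-test outcome.

#' Default marginal specification of the 20 putative moderators
#'
#' Continuous instruments are truncated normals (latent parameters calibrated
#' so the truncated, rounded scores reproduce the configured mean/SD) and may
#' load on a shared latent severity factor to induce realistic
#' intercorrelations; categorical moderators are independent draws with the
#' baseline frequencies of the pooled sample.
#'
#' @return named list of per-moderator marginal specifications.
#' @export
default_covariate_spec <- function() {
  cont <- function(mean, sd, lo, hi, loading = 0, integer = TRUE)
    list(type = "continuous", mean = mean, sd = sd, range = c(lo, hi),
         loading = loading, integer = integer)
  cat_ <- function(levels, probs)
    list(type = "categorical", levels = levels, probs = probs / sum(probs))
  yn <- function(p_yes) cat_(c("no", "yes"), c(1 - p_yes, p_yes))
  list(
    age               = cont(51.59, 8.55, 18, 80),
    gender            = cat_(c("male", "female"), c(1 - 0.6131, 0.6131)),
    relationship      = yn(0.7242),
    education         = cat_(c("none", "up_to_9y", "12_13y", "after_high_school"),
                             c(76, 164, 201, 39)),
    children          = yn(0.7976),
    lifetime_scid     = yn(0.4345),
    prev_psychotherapy  = yn(0.3611),
    prev_dep_medication = yn(0.2817),
    prev_pain_medication = yn(0.6389),
    sick_leave        = yn(0.6964),
    social_support    = cat_(c("little", "sufficient", "good", "very_good"),
                             c(142, 146, 147, 51)),
    internet_affinity = cont(14, 3, 4, 20),
    recruitment       = cat_(c("onsite", "online"), c(0.7063, 0.2937)),
    phq9_baseline     = cont(10.06, 4.55, 5, 27, loading = 0.6),
    hamd_baseline     = cont(11, 5, 0, 52, loading = 0.6),
    nrs_pain          = cont(6, 1.8, 0, 10),
    aqol              = cont(55, 15, 0, 100, loading = -0.6),
    pseq              = cont(35, 12, 0, 60, loading = -0.6),
    spe               = cont(1.5, 0.9, 0, 3),
    odi               = cont(35, 15, 0, 100)
  )
}

#' Default planted subgroup rules
#'
#' The ordered list of (predicate, standardized effect) pairs mirroring the
#' published six-node tree: splits on baseline PHQ-9 at 10 and 6, AQoL-6D at
#' 43 within the mild stratum, and PSEQ at 38 within the moderate-to-severe
#' stratum.
#'
#' @return list of rules, each `list(when = <predicate string>, d = <effect>)`.
#' @export
default_subgroup_rules <- function() {
  list(
    list(when = "phq9_baseline <= 6", d = -0.55),
    list(when = "phq9_baseline > 6 & phq9_baseline <= 10 & aqol <= 43", d = -0.44),
    list(when = "phq9_baseline > 6 & phq9_baseline <= 10 & aqol > 43",  d = -0.58),
    list(when = "phq9_baseline > 10 & phq9_baseline <= 15 & pseq <= 38", d = -1.31),
    list(when = "phq9_baseline > 10 & phq9_baseline <= 15 & pseq > 38",  d = 0.24),
    list(when = "phq9_baseline > 15", d = -0.58)
  )
}

#' Configuration of the synthetic-data generator
#'
#' @param n_per_trial integer pair, rows per trial (default 252 + 252 = 504).
#' @param arm_allocation probability of assignment to the intervention arm;
#'   allocation is exact (largest-remainder across trials), so the default
#'   253/504 reproduces the pooled 253/251 split.
#' @param covariate_spec per-moderator marginals, see [default_covariate_spec()].
#' @param true_subgroup_rules ordered list of planted (predicate, d) pairs;
#'   predicates must partition covariate space (checked at generation).
#' @param residual_sd SD of post-test noise on the PHQ-9 scale; also the
#'   reference SD converting planted standardized effects to raw points.
#' @param intercept control-arm grand mean offset of the outcome model
#'   `phq9_post = intercept + slope_baseline * phq9_baseline + ...`.
#' @param slope_baseline regression of post-test on baseline PHQ-9.
#' @param tau2_intercept,tau2_slope between-trial variances of the control
#'   mean and of the treatment effect, both on the raw PHQ-9 scale
#'   (the fitted meta-analytic model estimates tau2 on this scale).
#' @param missing_rate target marginal proportion of missing post-test values.
#' @param missing_logit_coefs named numeric vector of MAR dropout-model
#'   coefficients on (centred) baseline covariates; the intercept is
#'   calibrated to `missing_rate`.
#' @param n_external rows of the external validation trial.
#' @param external_shift named list fixing covariate columns in the external
#'   trial (covariate-shift knob), e.g. `list(sick_leave = "yes")`.
#' @param seed integer seed; all generation is deterministic given it.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_per_trial = c(252L, 252L),
                             arm_allocation = 253 / 504,
                             covariate_spec = default_covariate_spec(),
                             true_subgroup_rules = default_subgroup_rules(),
                             residual_sd = 4.55,
                             intercept = 4.1,
                             slope_baseline = 0.5,
                             tau2_intercept = 2.2,
                             tau2_slope = 0.48,
                             missing_rate = 0.20,
                             missing_logit_coefs = c(phq9_baseline = 0.07,
                                                     sick_leave = 0.3),
                             n_external = 76L,
                             external_shift = NULL,
                             seed = 1L) {
  stopifnot(length(n_per_trial) == 2, all(n_per_trial >= 1),
            arm_allocation >= 0, arm_allocation <= 1,
            residual_sd > 0, tau2_intercept >= 0, tau2_slope >= 0,
            missing_rate >= 0, missing_rate < 1, n_external >= 1)
  validate_covariate_spec(covariate_spec)
  if (!length(true_subgroup_rules))
    stop("true_subgroup_rules must contain at least one rule")
  cfg <- list(n_per_trial = as.integer(n_per_trial),
              arm_allocation = arm_allocation,
              covariate_spec = covariate_spec,
              true_subgroup_rules = true_subgroup_rules,
              residual_sd = residual_sd, intercept = intercept,
              slope_baseline = slope_baseline,
              tau2_intercept = tau2_intercept, tau2_slope = tau2_slope,
              missing_rate = missing_rate,
              missing_logit_coefs = missing_logit_coefs,
              n_external = as.integer(n_external),
              external_shift = external_shift,
              seed = as.integer(seed))
  class(cfg) <- "synthetic_config"
  cfg
}

validate_covariate_spec <- function(spec) {
  for (nm in names(spec)) {
    s <- spec[[nm]]
    if (s$type == "continuous") {
      ir <- INSTRUMENT_RANGES[[nm]]
      if (!is.null(ir) && (s$range[1] < ir[1] || s$range[2] > ir[2]))
        stop("covariate_spec range for '", nm, "' outside instrument range [",
             ir[1], ", ", ir[2], "]")
      if (s$sd <= 0) stop("covariate_spec sd for '", nm, "' must be positive")
    } else if (s$type == "categorical") {
      if (any(s$probs < 0) || abs(sum(s$probs) - 1) > 1e-8)
        stop("category probabilities for '", nm, "' must be a distribution")
      if (length(s$levels) != length(s$probs))
        stop("levels/probs length mismatch for '", nm, "'")
    } else stop("unknown covariate spec type for '", nm, "'")
  }
  invisible(TRUE)
}

# Evaluate planted rules on a covariate table; errors on overlap or gap.
match_subgroup_rules <- function(table, rules) {
  hits <- vapply(rules, function(r) {
    rep_len(eval(parse(text = r$when)[[1]], envir = table), nrow(table))
  }, logical(nrow(table)))
  if (nrow(table) == 1L) hits <- matrix(hits, nrow = 1L)
  nhit <- rowSums(hits)
  if (any(nhit == 0))
    stop("subgroup predicates leave gaps: ", sum(nhit == 0),
         " participant(s) match no rule")
  if (any(nhit > 1))
    stop("subgroup predicates overlap: ", sum(nhit > 1),
         " participant(s) match more than one rule")
  apply(hits, 1L, which.max)
}

# Run code with a private RNG stream, restoring the caller's state after.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

draw_covariates <- function(n, spec) {
  z <- stats::rnorm(n)                       # shared latent severity factor
  out <- list()
  for (nm in names(spec)) {
    s <- spec[[nm]]
    if (s$type == "continuous") {
      lam <- s$loading %||% 0
      t <- if (lam != 0) lam * z + sqrt(1 - lam^2) * stats::rnorm(n)
           else stats::rnorm(n)
      # Gaussian-copula mapping onto the calibrated truncated normal keeps the
      # configured marginal exact while preserving the factor correlation.
      cal <- calibrate_truncnorm(s$mean, s$sd, s$range[1], s$range[2])
      plo <- stats::pnorm(s$range[1], cal$mu, cal$sd)
      phi <- stats::pnorm(s$range[2], cal$mu, cal$sd)
      x <- stats::qnorm(plo + stats::pnorm(t) * (phi - plo), cal$mu, cal$sd)
      if (isTRUE(s$integer)) x <- round(x)
      out[[nm]] <- clamp(x, s$range[1], s$range[2])
    } else {
      out[[nm]] <- factor(sample(s$levels, n, replace = TRUE, prob = s$probs),
                          levels = s$levels)
    }
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

# Exact arm counts via largest remainder across trials, randomized within.
allocate_arms <- function(n_by_trial, p) {
  total_int <- round(p * sum(n_by_trial))
  base <- floor(p * n_by_trial)
  rem <- total_int - sum(base)
  if (rem > 0) {
    frac <- p * n_by_trial - base
    base[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
      base[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1L
  }
  unlist(lapply(seq_along(n_by_trial), function(g) {
    arm <- c(rep("intervention", base[g]),
             rep("control", n_by_trial[g] - base[g]))
    sample(arm)
  }))
}

generate_outcome <- function(table, config, trial_intercepts, trial_effects) {
  d <- vapply(config$true_subgroup_rules, function(r) r$d, numeric(1))
  grp <- match_subgroup_rules(table, config$true_subgroup_rules)
  treat <- as.numeric(table$arm == "intervention")
  g <- as.character(table$trial)
  mu <- config$intercept + trial_intercepts[g] +
    config$slope_baseline * table$phq9_baseline +
    treat * (trial_effects[g] + d[grp] * config$residual_sd)
  y <- mu + stats::rnorm(nrow(table), 0, config$residual_sd)
  round(clamp(y, 0, 27))
}

#' Generate the pooled two-trial participant table
#'
#' Draws covariates, assigns arms with exact counts, draws one trial-level
#' intercept and treatment-effect deviation per trial, and generates the
#' post-test outcome as
#' `intercept + u0_trial + slope * phq9_baseline +
#'  arm * (u1_trial + d_subgroup * residual_sd) + noise`,
#' rounded and truncated to the 0-27 PHQ-9 range. Deterministic given
#' `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @return data frame (`participant_table`) with id, trial, arm, the 20
#'   moderators, and complete `phq9_post`.
#' @export
generate_trial_pair <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    n <- sum(config$n_per_trial)
    trial <- factor(rep(c("trial_A", "trial_B"), config$n_per_trial),
                    levels = c("trial_A", "trial_B", "external"))
    covs <- draw_covariates(n, config$covariate_spec)
    tab <- data.frame(
      id = sprintf("P%04d", seq_len(n)),
      trial = trial,
      arm = factor(allocate_arms(config$n_per_trial, config$arm_allocation),
                   levels = c("control", "intervention")),
      covs, stringsAsFactors = FALSE)
    u0 <- stats::rnorm(2, 0, sqrt(config$tau2_intercept))
    u1 <- stats::rnorm(2, 0, sqrt(config$tau2_slope))
    names(u0) <- names(u1) <- c("trial_A", "trial_B")
    tab$phq9_post <- generate_outcome(tab, config, u0, u1)
    class(tab) <- c("participant_table", class(tab))
    tab
  })
}

#' Mask the post-test outcome missing-at-random
#'
#' Sets `phq9_post` to `NA` with probability
#' `plogis(alpha + sum(coefs * covariates))`, where covariates are centred
#' (continuous) or yes/second-level indicators (categorical), and the
#' intercept `alpha` is calibrated by bisection so the expected marginal
#' missingness equals `missing_rate`. Only always-observed baseline columns
#' enter the dropout model, so missingness is MAR by construction. The input
#' table is not modified.
#'
#' @param table complete participant table.
#' @param config a [synthetic_config()]; uses `missing_rate`,
#'   `missing_logit_coefs`, `seed`.
#' @return a copy of `table` with `NA`s planted in `phq9_post`.
#' @export
apply_mar_missingness <- function(table, config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (any(is.na(table$phq9_post)))
    stop("table already contains missing phq9_post values")
  if (config$missing_rate < 0 || config$missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  out <- table
  if (config$missing_rate == 0) return(out)
  eta <- rep(0, nrow(table))
  for (nm in names(config$missing_logit_coefs)) {
    x <- table[[nm]]
    if (is.null(x)) stop("missingness covariate '", nm, "' not in table")
    v <- if (is.factor(x)) as.numeric(x == levels(x)[nlevels(x)])
         else as.numeric(scale(x, scale = FALSE))
    eta <- eta + config$missing_logit_coefs[[nm]] * v
  }
  f <- function(a) mean(stats::plogis(a + eta)) - config$missing_rate
  alpha <- stats::uniroot(f, c(-30, 30), tol = 1e-10)$root
  with_seed(config$seed + 1L, {
    miss <- stats::runif(nrow(table)) < stats::plogis(alpha + eta)
    out$phq9_post[miss] <- NA
  })
  out
}

#' Generate the external validation trial
#'
#' Single-trial table (default n = 76, trial = "external") drawn from the same
#' structural model with its own trial-level intercept and effect draw.
#' `config$external_shift` fixes covariate columns to constants (e.g. all
#' participants on sick leave) to emulate the population shift of the external
#' pilot trial.
#'
#' @param config a [synthetic_config()].
#' @return complete participant table with `trial == "external"`.
#' @export
generate_external_trial <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed + 2L, {
    n <- config$n_external
    covs <- draw_covariates(n, config$covariate_spec)
    tab <- data.frame(
      id = sprintf("E%04d", seq_len(n)),
      trial = factor(rep("external", n),
                     levels = c("trial_A", "trial_B", "external")),
      arm = factor(allocate_arms(n, config$arm_allocation),
                   levels = c("control", "intervention")),
      covs, stringsAsFactors = FALSE)
    for (nm in names(config$external_shift)) {
      val <- config$external_shift[[nm]]
      tab[[nm]] <- if (is.factor(tab[[nm]]))
        factor(rep(val, n), levels = levels(tab[[nm]])) else rep(val, n)
    }
    u0 <- stats::rnorm(1, 0, sqrt(config$tau2_intercept))
    u1 <- stats::rnorm(1, 0, sqrt(config$tau2_slope))
    names(u0) <- names(u1) <- "external"
    tab$phq9_post <- generate_outcome(tab, config, u0, u1)
    class(tab) <- c("participant_table", class(tab))
    tab
  })
}

#' Canonical names of the 20 putative moderators
#' @return character vector.
#' @export
moderator_names <- function() names(default_covariate_spec())
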