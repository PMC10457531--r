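# One-stage meta-analytic average treatment effect, standardized effect
# sizes, reliable-change classification, univariate treatment-moderator
# interactions, and the percentile change-score analysis.

treat_indicator <- function(table) as.numeric(table$arm == "intervention")

pooled_baseline_sd <- function(stack) {
  tab <- if (inherits(stack, "imputed_stack")) stack$tables[[1]] else stack
  stats::sd(tab$phq9_baseline)
}

#' Standardize a raw effect to Cohen's d
#'
#' @param beta adjusted raw-scale group difference (PHQ-9 points).
#' @param beta_ci length-2 CI for beta, or `NULL`.
#' @param sd_standardizer positive SD used for standardization (by default
#'   the pooled observed baseline SD in callers).
#' @return object of class `effect_size` with `d`, `ci_low`, `ci_high`,
#'   `beta`, `sd_standardizer`. Negative d favors the intervention.
#' @export
cohens_d <- function(beta, beta_ci = NULL, sd_standardizer) {
  if (!is.numeric(sd_standardizer) || sd_standardizer <= 0)
    stop("sd_standardizer must be positive")
  ci <- if (is.null(beta_ci)) c(NA_real_, NA_real_)
        else sort(beta_ci / sd_standardizer)
  structure(list(d = beta / sd_standardizer, ci_low = ci[1], ci_high = ci[2],
                 beta = beta, sd_standardizer = sd_standardizer),
            class = "effect_size")
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("d = %.2f (95%% CI %.2f to %.2f); beta = %.2f, SD = %.2f\n",
              x$d, x$ci_low, x$ci_high, x$beta, x$sd_standardizer))
  invisible(x)
}

ate_single_fit <- function(table, prior) {
  tab <- table
  tab$treat <- treat_indicator(tab)
  fit_mpl_lmm(phq9_post ~ trial:phq9_baseline + treat, tab,
              group = "trial", random = ~ 1 + treat, prior = prior)
}

#' One-stage meta-analytic average treatment effect
#'
#' Per imputation, fits the penalized multilevel model
#' `phq9_post ~ trial-stratified baseline + treatment` with random trial
#' intercepts and trial-specific treatment slopes, pools the treatment
#' coefficient by Rubin's rules, and converts it to Cohen's d.
#'
#' @param stack an `imputed_stack` (or a complete table, treated as m = 1).
#' @param prior [wishart_prior()] used in every per-imputation fit.
#' @param sd_standardizer SD for the d conversion; default pooled observed
#'   baseline PHQ-9 SD.
#' @return list with `pooled` ([rubin_pool()] result for the raw treatment
#'   coefficient), `effect_size`, `tau2_intercept`, `tau2_slope` (averaged
#'   across imputations), `fits_converged`.
#' @export
estimate_ate <- function(stack, prior = wishart_prior(),
                         sd_standardizer = NULL) {
  stack <- as_imputed_stack(stack)
  sd_std <- sd_standardizer %||% pooled_baseline_sd(stack)
  fits <- lapply(stack$tables, ate_single_fit, prior = prior)
  est <- vapply(fits, function(f) f$fixed_coefs[["treat"]], numeric(1))
  vr <- vapply(fits, function(f) f$fixed_se[["treat"]]^2, numeric(1))
  pooled <- rubin_pool(est, vr)
  es <- cohens_d(pooled$estimate, c(pooled$ci_low, pooled$ci_high), sd_std)
  list(pooled = pooled, effect_size = es,
       tau2_intercept = mean(vapply(fits, function(f) f$ranef_cov[1, 1],
                                    numeric(1))),
       tau2_slope = mean(vapply(fits, function(f) f$ranef_cov[2, 2],
                                numeric(1))),
       fits_converged = all(vapply(fits, `[[`, logical(1), "converged")))
}

#' Reliable change configuration
#'
#' @param reliability test-retest reliability of the PHQ-9 entering the
#'   standard error of measurement (default 0.84).
#' @param sd_baseline SD used in the index; `NULL` means the pooled observed
#'   baseline SD of the analyzed sample.
#' @param z_crit critical value (default 1.96).
#' @return object of class `rci_config`.
#' @export
rci_config <- function(reliability = 0.84, sd_baseline = NULL,
                       z_crit = 1.96) {
  if (reliability <= 0 || reliability >= 1)
    stop("reliability must lie in (0, 1)")
  if (!is.null(sd_baseline) && sd_baseline <= 0)
    stop("sd_baseline must be positive")
  structure(list(reliability = reliability, sd_baseline = sd_baseline,
                 z_crit = z_crit), class = "rci_config")
}

#' Reliable change classification and arm comparison
#'
#' Computes the reliable change index
#' `RC = (post - baseline) / (sd_baseline * sqrt(2 * (1 - reliability)))`
#' per participant; reliable improvement is `RC < -z_crit`. When given a
#' stack, classification runs per imputation and the arm comparison is a
#' pooled linear-probability contrast (Rubin's rules); counts are rounded
#' across imputations.
#'
#' @param stack an `imputed_stack` or complete table.
#' @param config an [rci_config()].
#' @return list with `se_diff`, `threshold` (raw-change threshold
#'   `z_crit * se_diff`), `by_arm` (data frame of n, improved count, integer
#'   percent per arm), `comparison` (pooled arm contrast on the improvement
#'   indicator), and `rc` (per-participant RC values, first imputation).
#' @export
reliable_change <- function(stack, config = rci_config()) {
  stopifnot(inherits(config, "rci_config"))
  stack <- as_imputed_stack(stack)
  sd_b <- config$sd_baseline %||% pooled_baseline_sd(stack)
  se_diff <- sd_b * sqrt(2 * (1 - config$reliability))
  per_imp <- lapply(stack$tables, function(tab) {
    rc <- (tab$phq9_post - tab$phq9_baseline) / se_diff
    improved <- rc < -config$z_crit
    fit <- stats::lm(improved ~ arm, data = tab)
    sm <- summary(fit)$coefficients
    list(rc = rc, improved = improved,
         est = sm["armintervention", "Estimate"],
         var = sm["armintervention", "Std. Error"]^2,
         counts = tapply(improved, tab$arm, sum),
         n = tapply(improved, tab$arm, length))
  })
  counts <- round(rowMeans(vapply(per_imp, function(x) x$counts, numeric(2))))
  n <- per_imp[[1]]$n
  pooled <- rubin_pool(vapply(per_imp, `[[`, numeric(1), "est"),
                       vapply(per_imp, `[[`, numeric(1), "var"))
  by_arm <- data.frame(arm = names(n), n = as.integer(n),
                       improved = as.integer(counts),
                       percent = as.integer(round(100 * counts / n)))
  list(se_diff = se_diff, threshold = config$z_crit * se_diff,
       by_arm = by_arm, comparison = pooled, rc = per_imp[[1]]$rc)
}

#' Univariate treatment-moderator interaction
#'
#' Per imputation fits `phq9_post ~ baseline adjustment + treatment +
#' moderator + treatment:moderator` with either the penalized multilevel
#' engine (random trial intercepts and trial-specific treatment slopes) or
#' the trial-stratified OLS engine with CR2 cluster-robust variance;
#' interaction coefficient, SE and test pooled by Rubin's rules. Continuous
#' moderators are standardized, so the coefficient is per moderator SD;
#' binary moderators stay 0/1.
#'
#' @param stack an `imputed_stack` or complete table.
#' @param moderator moderator column name (numeric or 2-level factor).
#' @param engine `"mpl_lmm"` or `"ols_cr2"`.
#' @param prior prior for the mixed engine.
#' @return object of class `moderator_result`: `moderator`,
#'   `beta_interaction`, `se`, `t`, `p`, `df`, `tau2_intercept`,
#'   `tau2_slope` (mixed engine), `subgroup_effects` (binary moderators),
#'   `engine`.
#' @export
univariate_moderation <- function(stack, moderator,
                                  engine = c("mpl_lmm", "ols_cr2"),
                                  prior = wishart_prior()) {
  engine <- match.arg(engine)
  stack <- as_imputed_stack(stack)
  sd_std <- pooled_baseline_sd(stack)
  prep <- function(tab) {
    x <- tab[[moderator]]
    if (is.null(x)) stop("moderator '", moderator, "' not in table")
    if (is.factor(x)) {
      if (nlevels(droplevels(x)) < 2) stop("moderator '", moderator,
                                           "' is constant")
      if (nlevels(droplevels(x)) > 2)
        stop("moderator '", moderator, "' has more than 2 levels; ",
             "dichotomize before the univariate analysis")
      m <- as.numeric(droplevels(x)) - 1
    } else {
      if (stats::sd(x) == 0) stop("moderator '", moderator, "' is constant")
      m <- drop(scale(x))
    }
    tab$mod <- m
    tab$treat <- treat_indicator(tab)
    if (abs(stats::cor(tab$mod, tab$treat)) > 0.999)
      stop("moderator '", moderator, "' is collinear with treatment")
    tab
  }
  base_adj <- if (moderator == "phq9_baseline") NULL else "trial:phq9_baseline"
  res <- lapply(stack$tables, function(tab) {
    tab <- prep(tab)
    if (engine == "mpl_lmm") {
      rhs <- paste(c(base_adj, "treat * mod"), collapse = " + ")
      f <- fit_mpl_lmm(stats::as.formula(paste("phq9_post ~", rhs)), tab,
                       group = "trial", random = ~ 1 + treat, prior = prior)
      list(est = f$fixed_coefs[["treat:mod"]], var = f$fixed_se[["treat:mod"]]^2,
           df = Inf, t2i = f$ranef_cov[1, 1], t2s = f$ranef_cov[2, 2])
    } else {
      rhs <- paste(c("trial", base_adj, "treat * mod"), collapse = " + ")
      f <- fit_ols_cr2(stats::as.formula(paste("phq9_post ~", rhs)), tab,
                       cluster = "trial")
      list(est = f$coef[["treat:mod"]], var = f$se[["treat:mod"]]^2,
           df = f$df[["treat:mod"]], t2i = NA_real_, t2s = NA_real_)
    }
  })
  pooled <- rubin_pool(vapply(res, `[[`, numeric(1), "est"),
                       vapply(res, `[[`, numeric(1), "var"),
                       df_com = stats::median(vapply(res, `[[`, numeric(1),
                                                     "df")))
  sub_eff <- NULL
  tab1 <- stack$tables[[1]]
  if (is.factor(tab1[[moderator]]) || is_binary01(tab1[[moderator]])) {
    sub_eff <- lapply(split(seq_len(nrow(tab1)), tab1[[moderator]]),
                      function(i) {
      sub <- lapply(stack$tables, function(t) t[i, ])
      substack <- structure(list(tables = sub, methods = stack$methods),
                            class = "imputed_stack")
      ests <- vapply(substack$tables, function(t) {
        t$treat <- treat_indicator(t)
        f <- stats::lm(phq9_post ~ trial + phq9_baseline + treat, t)
        s <- summary(f)$coefficients
        c(s["treat", "Estimate"], s["treat", "Std. Error"]^2)
      }, numeric(2))
      pl <- rubin_pool(ests[1, ], ests[2, ])
      cohens_d(pl$estimate, c(pl$ci_low, pl$ci_high), sd_std)
    })
  }
  structure(list(moderator = moderator, beta_interaction = pooled$estimate,
                 se = pooled$se, t = pooled$t, p = pooled$p, df = pooled$df,
                 tau2_intercept = mean(vapply(res, `[[`, numeric(1), "t2i")),
                 tau2_slope = mean(vapply(res, `[[`, numeric(1), "t2s")),
                 subgroup_effects = sub_eff, engine = engine),
            class = "moderator_result")
}

#' @export
print.moderator_result <- function(x, ...) {
  cat(sprintf("%s [%s]: beta_int = %.3f (SE %.3f), t = %.3f, p = %.4f\n",
              x$moderator, x$engine, x$beta_interaction, x$se, x$t, x$p))
  if (!is.na(x$tau2_intercept))
    cat(sprintf("  tau2_Intercept = %.3f, tau2_Slope = %.3f\n",
                x$tau2_intercept, x$tau2_slope))
  invisible(x)
}

#' Percentile change-score analysis
#'
#' Assigns participants to the five percentile bands of a continuous
#' moderator (<20th, 20-40th, 40-60th, 60-80th, >80th, quantiles of the
#' pooled baseline distribution, boundary values to the lower band), reports
#' per band and arm the n, mean change score (post - baseline) and its SE,
#' tests the overall band-by-treatment interaction, and returns pairwise
#' band contrasts of the arm difference.
#'
#' @param stack an `imputed_stack` or complete table.
#' @param moderator continuous column with at least 5 distinct values.
#' @return object of class `percentile_table`.
#' @export
percentile_change_analysis <- function(stack, moderator) {
  stack <- as_imputed_stack(stack)
  tab1 <- stack$tables[[1]]
  x <- tab1[[moderator]]
  if (is.null(x)) stop("moderator '", moderator, "' not in table")
  if (is.factor(x) || length(unique(x)) < 5)
    stop("moderator '", moderator, "' has too few distinct values; ",
         "treat it as categorical instead")
  qs <- stats::quantile(x, c(0.2, 0.4, 0.6, 0.8), type = 7)
  band_of <- function(v) {
    findInterval(v, qs, left.open = TRUE) + 1L   # boundary -> lower band
  }
  band_labels <- c("<20th", "20-40th", "40-60th", "60-80th", ">80th")
  band <- factor(band_labels[band_of(x)], levels = band_labels)

  per_imp <- lapply(stack$tables, function(tab) {
    ch <- tab$phq9_post - tab$phq9_baseline
    data.frame(band = band, arm = tab$arm, change = ch,
               treat = treat_indicator(tab))
  })
  cell <- do.call(rbind, lapply(seq_along(per_imp), function(i) {
    df <- per_imp[[i]]
    agg <- stats::aggregate(change ~ band + arm, df,
                            function(v) c(n = length(v), mean = mean(v),
                                          se = stats::sd(v) / sqrt(length(v))))
    data.frame(imp = i, band = agg$band, arm = agg$arm,
               n = agg$change[, "n"], mean = agg$change[, "mean"],
               se = agg$change[, "se"])
  }))
  bands <- stats::aggregate(cbind(mean, se) ~ band + arm, cell, mean)
  nn <- stats::aggregate(n ~ band + arm, cell[cell$imp == 1, ], identity)
  bands <- merge(nn, bands, by = c("band", "arm"), sort = FALSE)
  bands <- bands[order(bands$band, bands$arm), ]

  # overall band x treatment heterogeneity: F test pooled across imputations
  het <- vapply(per_imp, function(df) {
    tryCatch({
      full <- stats::lm(change ~ band * treat, df)
      red <- stats::lm(change ~ band + treat, df)
      av <- stats::anova(red, full)
      c(stat = av$F[2], p = av$`Pr(>F)`[2])
    }, error = function(e) c(stat = NA_real_, p = NA_real_))
  }, numeric(2))
  # pairwise band contrasts of the arm difference
  lv <- levels(band)
  pairs <- utils::combn(lv, 2)
  pair_p <- apply(pairs, 2, function(pr) {
    ps <- vapply(per_imp, function(df) {
      sub <- df[df$band %in% pr, ]
      sub$band <- droplevels(sub$band)
      f <- suppressWarnings(
        summary(stats::lm(change ~ band * treat, sub))$coefficients)
      row <- grep(":treat", rownames(f))
      if (length(row) != 1) NA_real_ else f[row, "Pr(>|t|)"]
    }, numeric(1))
    stats::median(ps)
  })
  structure(list(bands = bands, quantiles = qs,
                 heterogeneity = list(statistic = mean(het["stat", ]),
                                      p = stats::median(het["p", ])),
                 pairwise = data.frame(band_a = pairs[1, ],
                                       band_b = pairs[2, ], p = pair_p),
                 moderator = moderator),
            class = "percentile_table")
}

#' @export
print.percentile_table <- function(x, ...) {
  cat("Percentile change-score analysis of", x$moderator, "\n")
  print(x$bands, row.names = FALSE)
  cat(sprintf("Band x treatment heterogeneity: F = %.3f, p = %.3f\n",
              x$heterogeneity$statistic, x$heterogeneity$p))
  invisible(x)
}
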