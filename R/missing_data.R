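# Multilevel multiple imputation by chained equations: groupwise (per-arm)
# conditional models, predictor-matrix pruning by pairwise correlation,
# two-level normal draws for numeric columns (trial random intercept,
# Wishart-penalized estimation), predictive mean matching for categorical
# columns, and Rubin's-rules pooling.

#' Imputation configuration
#'
#' @param m number of imputations (default 50).
#' @param n_iterations chained-equation sweeps per imputation (default 10;
#'   automatically 1 when a single column is incomplete, since the chain is
#'   then degenerate).
#' @param prune_threshold minimum absolute pairwise-complete correlation for a
#'   column to stay in the predictor matrix (default 0.05).
#' @param pmm_donors donor-pool size for predictive mean matching (default 5).
#' @param groupwise_by fully observed column splitting the imputation models
#'   (default `"arm"`).
#' @param prior [wishart_prior()] for the two-level normal model.
#' @param seed integer seed.
#' @return object of class `imputation_config`.
#' @export
imputation_config <- function(m = 50L, n_iterations = 10L,
                              prune_threshold = 0.05, pmm_donors = 5L,
                              groupwise_by = "arm",
                              prior = wishart_prior(), seed = 1L) {
  stopifnot(m >= 1, n_iterations >= 1, prune_threshold >= 0,
            prune_threshold < 1, pmm_donors >= 1)
  structure(list(m = as.integer(m), n_iterations = as.integer(n_iterations),
                 prune_threshold = prune_threshold,
                 pmm_donors = as.integer(pmm_donors),
                 groupwise_by = groupwise_by, prior = prior,
                 seed = as.integer(seed)),
            class = "imputation_config")
}

numeric_view <- function(x) if (is.factor(x)) as.numeric(x) else as.numeric(x)

#' Build the pruned predictor matrix
#'
#' For each column with missing values, flags as predictors all auxiliary
#' columns whose pairwise-complete absolute correlation with it reaches the
#' pruning threshold. `trial` and the groupwise column are always retained as
#' structural variables; constant columns are excluded with a warning
#' (correlation treated as zero).
#'
#' @param table participant table.
#' @param config an [imputation_config()].
#' @return binary matrix, one row per incomplete column, one column per
#'   candidate predictor.
#' @export
build_predictor_matrix <- function(table, config = imputation_config()) {
  cols <- setdiff(names(table), "id")
  targets <- cols[vapply(cols, function(c) anyNA(table[[c]]), logical(1))]
  structural <- intersect(c("trial", config$groupwise_by), cols)
  P <- matrix(0L, length(targets), length(cols),
              dimnames = list(targets, cols))
  for (t in targets) {
    xt <- numeric_view(table[[t]])
    if (all(is.na(xt))) stop("column '", t, "' has zero observed values")
    for (a in setdiff(cols, t)) {
      xa <- numeric_view(table[[a]])
      if (stats::sd(xa, na.rm = TRUE) == 0 || all(is.na(xa))) {
        warning("constant auxiliary column '", a,
                "' excluded from predictors of '", t, "'")
        next
      }
      ok <- stats::complete.cases(xt, xa)
      r <- if (sum(ok) >= 3 && stats::sd(xt[ok]) > 0 && stats::sd(xa[ok]) > 0)
        stats::cor(xt[ok], xa[ok]) else 0
      if (is.na(r)) r <- 0
      if (abs(r) >= config$prune_threshold) P[t, a] <- 1L
    }
    P[t, structural] <- 1L
    P[t, t] <- 0L
  }
  P
}

# Design matrix for given predictor columns, aliased columns dropped.
imputation_design <- function(table, predictors) {
  if (!length(predictors)) return(matrix(1, nrow(table), 1,
                                         dimnames = list(NULL, "(Intercept)")))
  df <- droplevels(table[predictors])
  X <- stats::model.matrix(~., df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  X
}

# Reduce a design to columns of full rank on the fitting rows (columns that
# are constant or aliased within the current arm group are dropped).
drop_aliased_on <- function(X, rows) {
  qrX <- qr(X[rows, , drop = FALSE])
  X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
}

# One two-level-normal draw: posterior-predictive values for rows `mis` given
# observed rows `obs` (both logical over table rows within the current group).
draw_two_level_normal <- function(y, X, trial, obs, mis, prior) {
  X <- drop_aliased_on(X, obs)
  fit <- fit_mpl_lmm(y ~ X - 1, data.frame(y = y[obs],
                                           X = I(X[obs, , drop = FALSE]),
                                           trial = trial[obs]),
                     group = "trial", random = ~1, prior = prior,
                     control = list(maxit = 400, reltol = 1e-8))
  beta_star <- fit$fixed_coefs +
    drop(t(chol(fit$vcov + diag(1e-12, ncol(fit$vcov)))) %*%
           stats::rnorm(length(fit$fixed_coefs)))
  df_res <- max(sum(obs) - length(beta_star), 2)
  sigma2_star <- fit$sigma2 * df_res / stats::rchisq(1, df_res)
  re <- fit$ranef[, 1]
  re_mis <- ifelse(as.character(trial[mis]) %in% names(re),
                   re[as.character(trial[mis])], 0)
  drop(X[mis, , drop = FALSE] %*% beta_star) + re_mis +
    stats::rnorm(sum(mis), 0, sqrt(sigma2_star))
}

# Predictive mean matching draw for a categorical column.
draw_pmm <- function(yfac, X, obs, mis, donors) {
  X <- drop_aliased_on(X, obs)
  ynum <- as.numeric(yfac)
  b <- stats::lm.fit(X[obs, , drop = FALSE], ynum[obs])$coefficients
  b[is.na(b)] <- 0
  pred <- drop(X %*% b)
  obs_idx <- which(obs)
  vapply(which(mis), function(i) {
    d <- abs(pred[obs_idx] - pred[i])
    pool <- obs_idx[order(d)[seq_len(min(donors, length(obs_idx)))]]
    as.integer(ynum[sample(pool, 1)])
  }, integer(1))
}

#' Multiply impute a participant table
#'
#' Chained-equation sweeps run separately within each level of the groupwise
#' column (by default the treatment arm). Numeric columns are drawn from the
#' posterior predictive of a two-level normal model with a trial random
#' intercept estimated by maximum penalized likelihood; categorical columns
#' are imputed by predictive mean matching on the linear predictor. Columns
#' are visited in increasing order of missingness. Deterministic given the
#' configured seed.
#'
#' @param table participant table with missing values.
#' @param config an [imputation_config()].
#' @return object of class `imputed_stack`: list with `tables` (m completed
#'   tables), `predictor_matrix`, `methods`, `trace`, `config`.
#' @export
impute <- function(table, config = imputation_config()) {
  gw <- config$groupwise_by
  if (anyNA(table[[gw]])) stop("groupwise column '", gw, "' has missing values")
  targets <- names(which(vapply(table, anyNA, logical(1))))
  methods <- vapply(names(table), function(c) {
    if (!c %in% targets) "none"
    else if (is.factor(table[[c]])) "pmm" else "two-level-normal"
  }, character(1))
  if (!length(targets)) {
    stack <- structure(list(tables = rep(list(table), config$m),
                            predictor_matrix = matrix(0L, 0, ncol(table)),
                            methods = methods, trace = NULL, config = config),
                       class = "imputed_stack")
    return(stack)
  }
  P <- build_predictor_matrix(table, config)
  miss_frac <- vapply(targets, function(c) mean(is.na(table[[c]])), numeric(1))
  visit <- targets[order(miss_frac)]
  sweeps <- if (length(targets) == 1L) 1L else config$n_iterations
  ranges <- lapply(targets, function(c) INSTRUMENT_RANGES[[c]])
  names(ranges) <- targets

  with_seed(config$seed, {
    tables <- vector("list", config$m)
    trace <- list()
    for (mm in seq_len(config$m)) {
      tab <- table
      # initialize by random draws from the observed margin
      for (c in targets) {
        na_i <- is.na(tab[[c]])
        tab[[c]][na_i] <- sample(tab[[c]][!na_i], sum(na_i), replace = TRUE)
      }
      for (it in seq_len(sweeps)) {
        for (c in visit) {
          na_i <- is.na(table[[c]])
          preds <- names(which(P[c, ] == 1L))
          preds <- setdiff(preds, c(gw, "trial"))
          for (lvl in levels(droplevels(as.factor(table[[gw]])))) {
            in_g <- table[[gw]] == lvl
            obs <- in_g & !na_i
            mis <- in_g & na_i
            if (!any(mis)) next
            if (!any(obs)) stop("no observed values of '", c,
                                "' in group ", lvl)
            X <- imputation_design(tab, preds)
            if (methods[c] == "two-level-normal") {
              v <- draw_two_level_normal(tab[[c]], X, tab$trial, obs, mis,
                                         config$prior)
              rg <- ranges[[c]]
              if (!is.null(rg)) v <- clamp(round(v), rg[1], rg[2])
              tab[[c]][mis] <- v
            } else {
              lv <- draw_pmm(tab[[c]], X, obs, mis, config$pmm_donors)
              tab[[c]][mis] <- levels(tab[[c]])[lv]
            }
          }
          trace[[length(trace) + 1L]] <- data.frame(
            imputation = mm, iteration = it, column = c,
            mean = mean(numeric_view(tab[[c]])[na_i]),
            sd = stats::sd(numeric_view(tab[[c]])[na_i]))
        }
      }
      tables[[mm]] <- tab
    }
    structure(list(tables = tables, predictor_matrix = P, methods = methods,
                   trace = do.call(rbind, trace), config = config),
              class = "imputed_stack")
  })
}

#' @export
print.imputed_stack <- function(x, ...) {
  cat(sprintf("Imputed stack: m = %d tables, %d imputed column(s)\n",
              length(x$tables), sum(x$methods != "none")))
  imp <- names(x$methods)[x$methods != "none"]
  if (length(imp)) cat("  methods:", paste(imp, x$methods[imp],
                                           sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Pool estimates across imputations by Rubin's rules
#'
#' @param estimates per-imputation point estimates.
#' @param variances per-imputation squared standard errors.
#' @param df_com complete-data degrees of freedom for the Barnard-Rubin
#'   adjustment; `Inf` (default) gives the classical large-sample df.
#' @param conf_level confidence level for the interval.
#' @return object of class `pooled_estimate` with `estimate`, `within_var`,
#'   `between_var`, `total_var`, `se`, `df`, `t`, `p`, `ci_low`, `ci_high`,
#'   `m`.
#' @export
rubin_pool <- function(estimates, variances, df_com = Inf,
                       conf_level = 0.95) {
  m <- length(estimates)
  if (m == 0) stop("no estimates to pool")
  if (length(variances) != m) stop("estimates and variances differ in length")
  if (any(variances < 0)) stop("variances must be non-negative")
  est <- mean(estimates)
  W <- mean(variances)
  B <- if (m > 1) stats::var(estimates) else 0
  Tv <- W + (1 + 1 / m) * B
  if (m == 1 || B == 0) {
    df <- df_com
  } else {
    lam <- (1 + 1 / m) * B / Tv
    df_old <- (m - 1) / lam^2
    df <- if (is.finite(df_com)) {
      df_obs <- (df_com + 1) / (df_com + 3) * df_com * (1 - lam)
      1 / (1 / df_old + 1 / df_obs)
    } else df_old
  }
  se <- sqrt(Tv)
  tval <- if (se > 0) est / se else 0
  p <- if (is.finite(df)) 2 * stats::pt(-abs(tval), df)
       else 2 * stats::pnorm(-abs(tval))
  q <- if (is.finite(df)) stats::qt(1 - (1 - conf_level) / 2, df)
       else stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(estimate = est, within_var = W, between_var = B,
                 total_var = Tv, se = se, df = df, t = tval, p = p,
                 ci_low = est - q * se, ci_high = est + q * se, m = m),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf(
    "Pooled estimate (m = %d): %.4f (SE %.4f, df %.1f, t %.3f, p %.4g)\n",
    x$m, x$estimate, x$se, x$df, x$t, x$p))
  cat(sprintf("  95%% CI [%.4f, %.4f]; W = %.4f, B = %.4f, T = %.4f\n",
              x$ci_low, x$ci_high, x$within_var, x$between_var, x$total_var))
  invisible(x)
}

#' Aggregate an imputed stack into one completed table
#'
#' Each originally missing numeric cell becomes the across-imputation mean,
#' rounded to the instrument grid where the column has one; categorical cells
#' become the across-imputation mode with ties broken by first category
#' order. Observed cells pass through untouched. This is the single completed
#' dataset on which nonparametric stages (forest, tree) operate, since
#' Rubin's rules do not apply to them.
#'
#' @param stack an `imputed_stack`.
#' @return completed participant table.
#' @export
aggregate_stack <- function(stack) {
  stopifnot(inherits(stack, "imputed_stack"))
  tabs <- stack$tables
  out <- tabs[[1]]
  imp_cols <- names(stack$methods)[stack$methods != "none"]
  for (c in imp_cols) {
    vals <- vapply(tabs, function(t) numeric_view(t[[c]]),
                   numeric(nrow(out)))
    if (length(tabs) == 1L) vals <- matrix(vals, ncol = 1)
    if (is.factor(out[[c]])) {
      lev <- levels(out[[c]])
      mode_i <- apply(vals, 1, function(v) {
        tb <- tabulate(v, nbins = length(lev))
        which.max(tb)                       # ties: first category order
      })
      out[[c]] <- factor(lev[mode_i], levels = lev)
    } else {
      mn <- rowMeans(vals)
      rg <- INSTRUMENT_RANGES[[c]]
      out[[c]] <- if (!is.null(rg)) clamp(round(mn), rg[1], rg[2]) else mn
    }
  }
  out
}

# Wrap a complete table as a degenerate one-imputation stack; lets stack-based
# analyses run on complete data.
as_imputed_stack <- function(table) {
  if (inherits(table, "imputed_stack")) return(table)
  methods <- vapply(names(table), function(c) "none", character(1))
  structure(list(tables = list(table),
                 predictor_matrix = matrix(0L, 0, ncol(table)),
                 methods = methods, trace = NULL,
                 config = imputation_config(m = 1L)),
            class = "imputed_stack")
}
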