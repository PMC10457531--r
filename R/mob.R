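# Model-based recursive partitioning with a treatment-effect node model.
# Each node carries the Gaussian working model phq9_post ~ intercept +
# treatment; parameter instability along each candidate moderator is tested
# with a supLM score-fluctuation statistic (ordered variables) or a chi-square
# category statistic (categorical variables); Bonferroni-corrected p-values
# below alpha trigger an exhaustive cutpoint search minimizing the summed
# child SSE. Trial-level random effects are handled by an alternating
# global-deviation scheme: random effects are estimated globally by the
# penalized multilevel model given the current tree structure, subtracted,
# and the tree regrown on the deviations until assignments stabilize.

#' Control parameters for MOB trees
#'
#' @param alpha significance level for the parameter instability tests
#'   (default 0.05).
#' @param bonferroni multiply instability p-values by the number of tested
#'   partitioning variables ("pre-pruning", default `TRUE`).
#' @param min_node_size minimum observations per node (default 20; must be at
#'   least the number of node-model parameters + 1).
#' @param max_depth optional depth cap (`Inf` = none).
#' @param mixed_effects handle trial random effects by the alternating
#'   global-deviation scheme (default `TRUE` for standalone trees; forests
#'   run with `FALSE` on the aggregated table).
#' @param trim optional supLM trimming fraction; by default derived from
#'   `min_node_size / n` at each node.
#' @param node_baseline include baseline PHQ-9 as a covariate in the node
#'   model (default `FALSE`: the node model is intercept + treatment only,
#'   with baseline adjustment left to the global random-effects stage).
#'   Adjusting inside the node absorbs the prognostic severity gradient, so
#'   instability tests and cutpoint search respond to treatment-effect
#'   heterogeneity rather than prognosis.
#' @param max_cycles maximum alternation cycles (default 50).
#' @return object of class `mob_control`.
#' @export
mob_control <- function(alpha = 0.05, bonferroni = TRUE, min_node_size = 20L,
                        max_depth = Inf, mixed_effects = TRUE, trim = NULL,
                        node_baseline = FALSE, max_cycles = 50L) {
  stopifnot(alpha > 0, alpha < 1)
  min_par <- if (node_baseline) 4L else 3L
  if (min_node_size < min_par)
    stop("min_node_size must be >= number of node-model parameters + 1 (",
         min_par, ")")
  structure(list(alpha = alpha, bonferroni = bonferroni,
                 min_node_size = as.integer(min_node_size),
                 max_depth = max_depth, mixed_effects = mixed_effects,
                 trim = trim, node_baseline = node_baseline,
                 max_cycles = as.integer(max_cycles)),
            class = "mob_control")
}

# Gaussian node model: y ~ intercept [+ baseline] + treat, OLS, sigma2 by ML.
fit_node_model <- function(y, treat, baseline = NULL) {
  n <- length(y)
  if (is.null(baseline)) {
    if (length(unique(treat)) < 2) {
      coef <- c(`(Intercept)` = mean(y), treat = 0)
      r <- y - mean(y)
    } else {
      m0 <- mean(y[treat == 0]); m1 <- mean(y[treat == 1])
      coef <- c(`(Intercept)` = m0, treat = m1 - m0)
      r <- y - ifelse(treat == 1, m1, m0)
    }
    X <- cbind(`(Intercept)` = rep(1, n), treat = treat)
  } else {
    X <- cbind(`(Intercept)` = rep(1, n), phq9_baseline = baseline,
               treat = treat)
    ft <- stats::lm.fit(X, y)
    coef <- ft$coefficients
    coef[is.na(coef)] <- 0
    r <- y - drop(X %*% coef)
  }
  sigma2 <- max(mean(r^2), 1e-12)
  list(coef = coef, residuals = r, sigma2 = sigma2, n = n,
       sse = sum(r^2), X = X)
}

#' Per-observation score matrix of a node model
#'
#' Row i holds the derivative of observation i's Gaussian log-likelihood with
#' respect to the node-model parameters (intercept, treatment) at the fit:
#' `x_i * r_i / sigma2`. Columns sum to ~0 at the optimum.
#'
#' @param fit result of the internal node-model fit (list with `residuals`,
#'   `sigma2` and the design `X`), or any list with those fields.
#' @param table data with the rows the model was fitted on (needs `arm`).
#' @return n x k score matrix (k = 2, or 3 with the baseline-adjusted node
#'   model).
#' @export
node_scores <- function(fit, table) {
  if (length(fit$residuals) != nrow(table))
    stop("fit and table dimensions differ")
  X <- fit$X %||% cbind(`(Intercept)` = rep(1, nrow(table)),
                        treat = treat_indicator(table))
  X * (fit$residuals / fit$sigma2)
}

# ---- supLM null distribution -------------------------------------------
# Per k, simulate LM trajectories ||B(t)||^2/(t(1-t)) of a k-dimensional
# Brownian bridge on a fixed grid once (fixed internal seed) and cache the
# paths x grid matrix; any trimming window then reduces to a row maximum
# over the grid columns inside the window.
SUPLM_GRID <- 200L
SUPLM_PATHS <- 10000L
SUPLM_SEED <- 20260921L

suplm_null_paths <- function(k) {
  key <- paste0("suplm_k", k)
  hit <- .mobcate_cache[[key]]
  if (!is.null(hit)) return(hit)
  G <- SUPLM_GRID; P <- SUPLM_PATHS
  tt <- seq_len(G) / (G + 1)
  lm_mat <- with_seed(SUPLM_SEED + k, {
    acc <- matrix(0, P, G)
    step <- sqrt(1 / (G + 1))
    for (comp in seq_len(k)) {
      incr <- matrix(stats::rnorm(P * (G + 1), sd = step), P, G + 1)
      W <- t(apply(incr, 1, cumsum))
      B <- W[, seq_len(G)] - outer(W[, G + 1], tt)
      acc <- acc + B^2
    }
    sweep(acc, 2, tt * (1 - tt), "/")
  })
  .mobcate_cache[[key]] <- list(t = tt, lm = lm_mat)
  .mobcate_cache[[key]]
}

suplm_pvalue <- function(stat, k, tlo, thi) {
  tlo <- round(tlo, 2); thi <- round(thi, 2)  # window quantized for caching
  key <- sprintf("suplm_max_%d_%.2f_%.2f", k, tlo, thi)
  nullmax <- .mobcate_cache[[key]]
  if (is.null(nullmax)) {
    np <- suplm_null_paths(k)
    use <- which(np$t >= tlo & np$t <= thi)
    if (!length(use)) use <- which.min(abs(np$t - (tlo + thi) / 2))
    nullmax <- np$lm[, use[1]]
    for (j in use[-1]) nullmax <- pmax(nullmax, np$lm[, j])
    nullmax <- sort(nullmax)
    .mobcate_cache[[key]] <- nullmax
  }
  # right-tail proportion via binary search on the sorted null sample
  1 - findInterval(stat - 1e-12, nullmax) / length(nullmax)
}

#' supLM parameter-instability test along an ordered variable
#'
#' Sorts observations by `z`, forms the cumulative score process standardized
#' by the root information, and takes the supremum over admissible split
#' fractions of the LM statistic `||W(t)||^2 / (t (1 - t))`. The p-value
#' comes from the simulated supremum distribution of a Brownian bridge over
#' the same trimming window (10^4 paths, fixed internal seed).
#'
#' @param scores n x k score matrix (see [node_scores()]).
#' @param z ordered (numeric) partitioning variable.
#' @param trim trimming fraction in (0, 0.5); split fractions outside
#'   `[trim, 1 - trim]` are not considered.
#' @return list with `statistic`, `p`, `k`.
#' @export
suplm_test <- function(scores, z, trim = 0.1) {
  n <- nrow(scores); k <- ncol(scores)
  if (length(unique(z)) < 2) {
    warning("constant partitioning variable; no instability testable")
    return(list(statistic = 0, p = 1, k = k))
  }
  stopifnot(trim > 0, trim < 0.5)
  ord <- order(z)
  s <- scores[ord, , drop = FALSE]
  J <- crossprod(s) / n
  Jih <- sym_inv_sqrt(J)
  W <- apply(s %*% Jih, 2, cumsum) / sqrt(n)
  tt <- seq_len(n) / n
  # splits only between distinct z values, inside the trimming window
  zs <- z[ord]
  ok <- which(tt >= trim & tt <= 1 - trim & seq_len(n) < n &
                zs != c(zs[-1], Inf))
  if (!length(ok)) {
    return(list(statistic = 0, p = 1, k = k))
  }
  lm_t <- rowSums(W[ok, , drop = FALSE]^2) / (tt[ok] * (1 - tt[ok]))
  stat <- max(lm_t)
  list(statistic = stat, p = suplm_pvalue(stat, k, trim, 1 - trim), k = k)
}

#' Chi-square instability test for a categorical variable
#'
#' Sums the scores within each category and forms the quadratic form
#' `sum_c S_c' (n_c J)^{-1} S_c`, asymptotically chi-square with
#' `k (C - 1)` degrees of freedom under parameter stability.
#'
#' @param scores n x k score matrix.
#' @param z factor partitioning variable.
#' @return list with `statistic`, `p`, `df`.
#' @export
cat_instability_test <- function(scores, z) {
  z <- as.factor(z)
  counts <- table(z)
  if (any(counts == 0)) {
    warning("dropping empty categories: ",
            paste(names(counts)[counts == 0], collapse = ", "))
    z <- droplevels(z)
    counts <- table(z)
  }
  C <- nlevels(z); k <- ncol(scores)
  if (C < 2) return(list(statistic = 0, p = 1, df = 0))
  J <- crossprod(scores) / nrow(scores)
  Jinv <- tryCatch(solve(J), error = function(e) sym_inv_sqrt(J) %*%
                     sym_inv_sqrt(J))
  stat <- 0
  for (lv in levels(z)) {
    Sc <- colSums(scores[z == lv, , drop = FALSE])
    stat <- stat + drop(t(Sc) %*% Jinv %*% Sc) / counts[[lv]]
  }
  df <- k * (C - 1)
  list(statistic = stat, p = stats::pchisq(stat, df, lower.tail = FALSE),
       df = df)
}

#' Select the splitting variable from instability p-values
#'
#' Applies the Bonferroni correction over the number of tested variables
#' (capped at 1) when enabled and returns the variable with the smallest
#' adjusted p-value if it undercuts alpha, else `NULL`. Ties are broken by
#' the declared variable order.
#'
#' @param pvals named numeric vector of per-variable instability p-values.
#' @param control a [mob_control()].
#' @return list with `variable` (or `NULL`), `p_adjusted`.
#' @export
select_split_variable <- function(pvals, control = mob_control()) {
  if (!length(pvals)) stop("no instability p-values supplied")
  adj <- if (control$bonferroni) pmin(pvals * length(pvals), 1) else pvals
  best <- which.min(adj)           # which.min takes the first on ties
  if (adj[best] < control$alpha)
    list(variable = names(pvals)[best], p_adjusted = unname(adj[best]))
  else
    list(variable = NULL, p_adjusted = unname(adj[best]))
}

# SSE of the two-arm-means model per candidate split via cumulative sums.
ordered_split_scan <- function(y, treat, z, min_node) {
  ord <- order(z)
  y <- y[ord]; treat <- treat[ord]; zs <- z[ord]
  n <- length(y)
  cum <- function(v) cumsum(v)
  n1 <- cum(treat); n0 <- cum(1 - treat)
  s1 <- cum(y * treat); s0 <- cum(y * (1 - treat))
  q1 <- cum(y^2 * treat); q0 <- cum(y^2 * (1 - treat))
  N1 <- n1[n]; N0 <- n0[n]; S1 <- s1[n]; S0 <- s0[n]
  Q1 <- q1[n]; Q0 <- q0[n]
  sse_arm <- function(q, s, m) ifelse(m > 0, q - s^2 / pmax(m, 1), 0)
  i <- seq_len(n - 1)
  left <- sse_arm(q1[i], s1[i], n1[i]) + sse_arm(q0[i], s0[i], n0[i])
  right <- sse_arm(Q1 - q1[i], S1 - s1[i], N1 - n1[i]) +
    sse_arm(Q0 - q0[i], S0 - s0[i], N0 - n0[i])
  tot <- left + right
  admissible <- i >= min_node & (n - i) >= min_node &
    zs[i] != zs[i + 1] &
    n1[i] >= 1 & n0[i] >= 1 & (N1 - n1[i]) >= 1 & (N0 - n0[i]) >= 1
  if (!any(admissible)) return(NULL)
  best <- i[admissible][which.min(tot[admissible])]
  list(cutpoint = zs[best], sse = tot[best])
}

# General SSE scan with node-model covariates via cumulative crossprods.
ordered_split_scan_cov <- function(y, X, z, min_node) {
  ord <- order(z)
  y <- y[ord]; X <- X[ord, , drop = FALSE]; zs <- z[ord]
  n <- length(y); k <- ncol(X)
  cxx <- apply(X[, rep(seq_len(k), each = k)] *
                 X[, rep(seq_len(k), times = k)], 2, cumsum)
  cxy <- apply(X * y, 2, cumsum)
  cyy <- cumsum(y^2)
  XtX_tot <- matrix(cxx[n, ], k, k); Xty_tot <- cxy[n, ]; yy_tot <- cyy[n]
  treat_col <- which(colnames(X) == "treat")
  ctr <- cumsum(X[, treat_col])
  cand <- which(seq_len(n) >= min_node & (n - seq_len(n)) >= min_node &
                  seq_len(n) < n & zs != c(zs[-1], Inf) &
                  ctr >= 1 & (seq_len(n) - ctr) >= 1 &
                  (ctr[n] - ctr) >= 1 & ((n - seq_len(n)) - (ctr[n] - ctr)) >= 1)
  if (!length(cand)) return(NULL)
  sse_at <- function(i) {
    XtX_l <- matrix(cxx[i, ], k, k)
    sse_l <- tryCatch({
      b <- solve(XtX_l + diag(1e-10, k), cxy[i, ])
      cyy[i] - sum(b * cxy[i, ])
    }, error = function(e) Inf)
    XtX_r <- XtX_tot - XtX_l
    sse_r <- tryCatch({
      b <- solve(XtX_r + diag(1e-10, k), Xty_tot - cxy[i, ])
      (yy_tot - cyy[i]) - sum(b * (Xty_tot - cxy[i, ]))
    }, error = function(e) Inf)
    sse_l + sse_r
  }
  tot <- vapply(cand, sse_at, numeric(1))
  if (all(!is.finite(tot))) return(NULL)
  best <- cand[which.min(tot)]
  list(cutpoint = zs[best], sse = min(tot))
}

categorical_split_scan <- function(y, treat, z, min_node, baseline = NULL) {
  z <- droplevels(as.factor(z))
  lv <- levels(z)
  C <- length(lv)
  if (C < 2) return(NULL)
  sse_of <- function(left_set) {
    inl <- z %in% left_set
    if (sum(inl) < min_node || sum(!inl) < min_node) return(Inf)
    f <- function(idx) {
      if (length(unique(treat[idx])) < 2) return(Inf)
      fit_node_model(y[idx], treat[idx], baseline[idx])$sse
    }
    f(which(inl)) + f(which(!inl))
  }
  if (C <= 10) {
    # enumerate all binary partitions keeping level 1 on the left
    subsets <- lapply(seq_len(2^(C - 1) - 1) - 1L, function(code) {
      mask <- bitwAnd(code, 2^(seq_len(C - 1) - 1)) > 0
      lv[c(TRUE, mask)]
    })
    sses <- vapply(subsets, sse_of, numeric(1))
    if (all(!is.finite(sses))) return(NULL)
    best <- which.min(sses)
    list(left_categories = subsets[[best]], sse = sses[best])
  } else {
    # many categories: order by mean outcome and scan as ordered
    mu <- tapply(y, z, mean)
    ranked <- names(sort(mu))
    zord <- match(as.character(z), ranked)
    sc <- if (is.null(baseline)) ordered_split_scan(y, treat, zord, min_node)
          else ordered_split_scan_cov(
            y, cbind(`(Intercept)` = rep(1, length(y)),
                     phq9_baseline = baseline, treat = treat),
            zord, min_node)
    if (is.null(sc)) return(NULL)
    list(left_categories = ranked[seq_len(sc$cutpoint)], sse = sc$sse)
  }
}

#' Exhaustive cutpoint search for a selected variable
#'
#' Ordered variables: scans midpoints between consecutive distinct values and
#' minimizes the summed SSE of the two child node models, reporting the
#' largest left-child data value (so splits read "<= c"). Categorical
#' variables: all binary category partitions up to 10 levels, beyond that
#' categories are ordered by mean outcome and scanned as ordered. Splits
#' producing a child below `min_node_size` (or a child without both arms) are
#' inadmissible.
#'
#' @param table node data (needs `arm` and the outcome).
#' @param variable column to split on.
#' @param control a [mob_control()].
#' @param outcome outcome column name.
#' @return `NULL` if no admissible split, else a list with `cutpoint` (ordered)
#'   or `left_categories` (categorical) and `sse`.
#' @export
search_cutpoint <- function(table, variable, control = mob_control(),
                            outcome = "phq9_post") {
  y <- table[[outcome]]
  treat <- treat_indicator(table)
  z <- table[[variable]]
  baseline <- if (isTRUE(control$node_baseline)) table$phq9_baseline else NULL
  if (is.factor(z))
    categorical_split_scan(y, treat, z, control$min_node_size, baseline)
  else if (is.null(baseline))
    ordered_split_scan(y, treat, z, control$min_node_size)
  else
    ordered_split_scan_cov(
      y, cbind(`(Intercept)` = rep(1, length(y)),
               phq9_baseline = baseline, treat = treat),
      z, control$min_node_size)
}

# ---- tree growth --------------------------------------------------------

node_trim <- function(n, control) {
  tr <- control$trim %||% max(control$min_node_size / n, 0.1)
  min(max(tr, 0.01), 0.49)
}

grow_tree_once <- function(table, partitioning_vars, control, outcome,
                           depth = 1L, id_env = NULL) {
  if (is.null(id_env)) { id_env <- new.env(); id_env$next_id <- 1L }
  id <- id_env$next_id; id_env$next_id <- id + 1L
  y <- table[[outcome]]
  treat <- treat_indicator(table)
  baseline <- if (isTRUE(control$node_baseline)) table$phq9_baseline else NULL
  fit <- fit_node_model(y, treat, baseline)
  make_terminal <- function() list(id = id, terminal = TRUE, n = nrow(table),
                                   rows = table$.row, fit = fit)
  if (nrow(table) < 2 * control$min_node_size || depth > control$max_depth ||
      length(unique(treat)) < 2)
    return(make_terminal())
  sc <- node_scores(fit, table)
  pv <- vapply(partitioning_vars, function(v) {
    z <- table[[v]]
    res <- if (is.factor(z)) cat_instability_test(sc, droplevels(z))
           else suppressWarnings(
             suplm_test(sc, z, trim = node_trim(nrow(table), control)))
    res$p
  }, numeric(1))
  sel <- select_split_variable(pv, control)
  if (is.null(sel$variable)) return(make_terminal())
  sp <- search_cutpoint(table, sel$variable, control, outcome)
  if (is.null(sp)) return(make_terminal())
  z <- table[[sel$variable]]
  if (!is.null(sp$left_categories))
    attr(sp$left_categories, "all_levels") <- levels(as.factor(z))
  go_left <- if (!is.null(sp$left_categories)) z %in% sp$left_categories
             else z <= sp$cutpoint
  left <- grow_tree_once(table[go_left, , drop = FALSE], partitioning_vars,
                         control, outcome, depth + 1L, id_env)
  right <- grow_tree_once(table[!go_left, , drop = FALSE], partitioning_vars,
                          control, outcome, depth + 1L, id_env)
  list(id = id, terminal = FALSE, n = nrow(table),
       split_variable = sel$variable,
       cutpoint = sp$cutpoint %||% NA_real_,
       left_categories = sp$left_categories,
       p_adjusted = sel$p_adjusted, instability_p = pv,
       kids = list(left, right))
}

tree_assignments <- function(node, n) {
  out <- integer(n)
  walk <- function(nd) {
    if (nd$terminal) out[nd$rows] <<- nd$id
    else { walk(nd$kids[[1]]); walk(nd$kids[[2]]) }
  }
  walk(node)
  out
}

table_fingerprint <- function(table, outcome) {
  num <- vapply(table, is.numeric, logical(1))
  paste(nrow(table), ncol(table),
        signif(sum(vapply(table[num], sum, numeric(1))), 12),
        signif(sum(table[[outcome]]), 12), sep = "|")
}

#' Grow a multilevel model-based tree
#'
#' Recursive partitioning with the treatment-effect node model. With
#' `mixed_effects` on, trial random effects (intercept and treatment slope)
#' are estimated globally by the penalized multilevel model given the current
#' tree-implied fixed structure, their predicted contribution is subtracted
#' from the outcome, and the tree is regrown on the deviations; the two steps
#' alternate until node assignments stabilize (at most `max_cycles` cycles,
#' with a warning if they do not).
#'
#' Terminal nodes report the conditional average treatment effect as Cohen's
#' d (node treatment coefficient refitted on the original outcome, divided by
#' the pooled baseline SD of the training sample), its 95% CI, node size and
#' share of the sample, and reliable-improvement rates per arm.
#'
#' @param table complete participant table (typically [aggregate_stack()]
#'   output).
#' @param partitioning_vars candidate moderator columns.
#' @param control a [mob_control()].
#' @param outcome outcome column (default `"phq9_post"`).
#' @param prior [wishart_prior()] for the global random-effects stage.
#' @param rci [rci_config()] for terminal-node improvement rates.
#' @return object of class `mob_tree`.
#' @export
grow_mob_tree <- function(table, partitioning_vars, control = mob_control(),
                          outcome = "phq9_post", prior = wishart_prior(),
                          rci = rci_config()) {
  stopifnot(length(partitioning_vars) >= 1)
  if (anyNA(table[[outcome]]))
    stop("outcome contains missing values; aggregate or impute first")
  tab <- table
  tab$.row <- seq_len(nrow(tab))
  tab$.y_work <- tab[[outcome]]
  mixed_ok <- control$mixed_effects &&
    nlevels(droplevels(as.factor(tab$trial))) >= 2
  assign_prev <- NULL
  alternation_converged <- TRUE
  cycles <- 0L
  repeat {
    cycles <- cycles + 1L
    root <- grow_tree_once(tab, partitioning_vars, control, ".y_work")
    assign_cur <- tree_assignments(root, nrow(tab))
    if (!mixed_ok) break
    if (!is.null(assign_prev) && identical(assign_prev, assign_cur)) break
    if (cycles >= control$max_cycles) {
      warning("random-effects alternation did not converge within ",
              control$max_cycles, " cycles; returning last tree")
      alternation_converged <- FALSE
      break
    }
    assign_prev <- assign_cur
    gdat <- tab
    gdat$.node <- factor(assign_cur)
    gdat$.treat <- treat_indicator(gdat)
    gdat$.y <- gdat[[outcome]]
    fml <- if (nlevels(gdat$.node) > 1) {
      if (isTRUE(control$node_baseline))
        .y ~ 0 + .node + .node:phq9_baseline + .node:.treat
      else .y ~ 0 + .node + .node:.treat
    } else {
      if (isTRUE(control$node_baseline)) .y ~ phq9_baseline + .treat
      else .y ~ .treat
    }
    gfit <- suppressWarnings(
      fit_mpl_lmm(fml, gdat, group = "trial", random = ~ 1 + .treat,
                  prior = prior, drop_aliased = TRUE))
    tab$.y_work <- tab[[outcome]] - ranef_contribution(gfit)
  }

  sd_std <- stats::sd(tab$phq9_baseline)
  se_diff <- (rci$sd_baseline %||% sd_std) * sqrt(2 * (1 - rci$reliability))
  total_n <- nrow(tab)
  terminals <- list()
  decorate <- function(nd) {
    if (!nd$terminal) {
      nd$kids <- lapply(nd$kids, decorate)
      return(nd)
    }
    rows <- nd$rows
    y <- tab[[outcome]][rows]
    treat <- treat_indicator(tab)[rows]
    baseline <- if (isTRUE(control$node_baseline))
      tab$phq9_baseline[rows] else NULL
    fit <- fit_node_model(y, treat, baseline)  # reported on the original outcome
    n0 <- sum(treat == 0); n1 <- sum(treat == 1)
    kpar <- length(fit$coef)
    se_beta <- if (n0 > 0 && n1 > 0 && nd$n > kpar) {
      XtXinv <- tryCatch(solve(crossprod(fit$X)), error = function(e) NULL)
      if (is.null(XtXinv)) NA_real_
      else sqrt(sum(fit$residuals^2) / (nd$n - kpar) *
                  XtXinv["treat", "treat"])
    } else NA_real_
    beta <- fit$coef[["treat"]]
    es <- cohens_d(beta, beta + c(-1.96, 1.96) * se_beta, sd_std)
    rc <- (y - tab$phq9_baseline[rows]) / se_diff
    improved <- rc < -rci$z_crit
    imp_tab <- data.frame(
      arm = c("control", "intervention"),
      n = c(n0, n1),
      improved = c(sum(improved[treat == 0]), sum(improved[treat == 1])))
    imp_tab$percent <- as.integer(round(100 * imp_tab$improved /
                                          pmax(imp_tab$n, 1)))
    cmp_p <- if (n0 > 1 && n1 > 1 && stats::sd(improved) > 0)
      suppressWarnings(
        summary(stats::lm(improved ~ treat))$coefficients["treat", "Pr(>|t|)"])
    else NA_real_
    nd$fit <- fit
    nd$effect <- es
    nd$se_beta <- se_beta
    nd$percent_of_sample <- round(100 * nd$n / total_n, 1)
    nd$improvement <- imp_tab
    nd$improvement_p <- cmp_p
    terminals[[length(terminals) + 1L]] <<- nd
    nd
  }
  root <- decorate(root)
  structure(list(root = root, control = control, n = total_n,
                 outcome = outcome, partitioning_vars = partitioning_vars,
                 sd_standardizer = sd_std,
                 n_terminal = length(terminals),
                 terminal_ids = vapply(terminals, `[[`, integer(1), "id"),
                 alternation_converged = alternation_converged,
                 cycles = cycles,
                 fingerprint = table_fingerprint(table, outcome)),
            class = "mob_tree")
}

#' List internal splits of a tree
#'
#' @param tree a `mob_tree`.
#' @return data frame with one row per internal node: `id`, `variable`,
#'   `cutpoint`, `p_adjusted`, `n`.
#' @export
tree_splits <- function(tree) {
  out <- list()
  walk <- function(nd) {
    if (nd$terminal) return(invisible())
    out[[length(out) + 1L]] <<- data.frame(
      id = nd$id, variable = nd$split_variable,
      cutpoint = if (!is.null(nd$left_categories)) NA_real_ else nd$cutpoint,
      p_adjusted = nd$p_adjusted, n = nd$n)
    walk(nd$kids[[1]]); walk(nd$kids[[2]])
  }
  walk(tree$root)
  if (!length(out)) return(data.frame(id = integer(), variable = character(),
                                      cutpoint = numeric(),
                                      p_adjusted = numeric(), n = integer()))
  do.call(rbind, out)
}

#' Route new data through a fitted tree
#'
#' @param tree a `mob_tree`.
#' @param newdata table with all split variables and `arm`.
#' @param mode `"strict"` errors on a missing split variable value;
#'   `"lenient"` routes such rows to the larger child (logged via message).
#' @return list with `node` (terminal node id per row) and `prediction`
#'   (terminal node model evaluated at the row's arm).
#' @export
predict_tree <- function(tree, newdata, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  n <- nrow(newdata)
  node_id <- integer(n)
  pred <- numeric(n)
  treat <- treat_indicator(newdata)
  route <- function(nd, idx) {
    if (!length(idx)) return(invisible())
    if (nd$terminal) {
      node_id[idx] <<- nd$id
      p <- nd$fit$coef[["(Intercept)"]] + nd$fit$coef[["treat"]] * treat[idx]
      if ("phq9_baseline" %in% names(nd$fit$coef))
        p <- p + nd$fit$coef[["phq9_baseline"]] * newdata$phq9_baseline[idx]
      pred[idx] <<- p
      return(invisible())
    }
    z <- newdata[[nd$split_variable]][idx]
    if (is.null(z)) stop("split variable '", nd$split_variable,
                         "' missing from newdata")
    nas <- is.na(z)
    if (any(nas)) {
      if (mode == "strict")
        stop("missing value of split variable '", nd$split_variable,
             "' in row(s) ", paste(idx[nas], collapse = ", "))
      message("routing ", sum(nas), " row(s) with missing '",
              nd$split_variable, "' to the larger child")
    }
    if (!is.null(nd$left_categories)) {
      known <- c(nd$left_categories, tree_categories(nd))
      bad <- !nas & !(as.character(z) %in% known)
      if (any(bad))
        stop("unknown category '", as.character(z)[bad][1],
             "' of '", nd$split_variable, "' in row ", idx[bad][1])
      go_left <- as.character(z) %in% nd$left_categories
    } else {
      go_left <- !nas & z <= nd$cutpoint
    }
    if (any(nas)) {
      bigger_left <- nd$kids[[1]]$n >= nd$kids[[2]]$n
      go_left[nas] <- bigger_left
    }
    route(nd$kids[[1]], idx[go_left])
    route(nd$kids[[2]], idx[!go_left])
  }
  route(tree$root, seq_len(n))
  list(node = node_id, prediction = pred)
}

# categories known to a categorical split (left set plus those observed on
# the right during training, reconstructed from kids if recorded)
tree_categories <- function(nd) {
  attr(nd$left_categories, "all_levels") %||% character(0)
}

#' @export
print.mob_tree <- function(x, ...) {
  cat(sprintf("Model-based tree: %d terminal node(s), n = %d%s\n",
              x$n_terminal, x$n,
              if (x$control$mixed_effects)
                sprintf(" (random-effects alternation, %d cycle(s))",
                        x$cycles) else ""))
  pr <- function(nd, indent, label) {
    pad <- strrep("  ", indent)
    if (nd$terminal) {
      cat(sprintf("%s[%d] %s* n = %d (%.1f%%), d = %.2f [%.2f, %.2f]\n",
                  pad, nd$id, label, nd$n, nd$percent_of_sample,
                  nd$effect$d, nd$effect$ci_low, nd$effect$ci_high))
    } else {
      rule <- if (!is.null(nd$left_categories))
        paste0(nd$split_variable, " in {",
               paste(nd$left_categories, collapse = ","), "}")
      else sprintf("%s <= %g", nd$split_variable, nd$cutpoint)
      cat(sprintf("%s[%d] %ssplit %s (adj. p = %.2g)\n", pad, nd$id, label,
                  rule, nd$p_adjusted))
      pr(nd$kids[[1]], indent + 1, "yes: ")
      pr(nd$kids[[2]], indent + 1, "no:  ")
    }
  }
  pr(x$root, 0, "")
  invisible(x)
}
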