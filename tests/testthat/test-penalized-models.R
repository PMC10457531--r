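# Wishart penalty, MPL mixed models, CR2 OLS, LASSO interactions.

test_that("wishart_log_penalty matches its closed form", {
  pr <- wishart_prior(nu = 4, scale = 0.05)
  # q = 2, cov = scale matrix itself: ((nu-q-1)/2) log|cov| - tr(S^-1 cov)/2
  val <- wishart_log_penalty(diag(0.05, 2), pr)
  expect_equal(val, 0.5 * log(0.05^2) - 0.5 * 2, tolerance = 1e-12)
  # independent evaluation via eigenvalues on a non-trivial matrix
  C <- matrix(c(0.7, 0.2, 0.2, 0.4), 2)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(wishart_log_penalty(C, pr),
               ((4 - 2 - 1) / 2) * sum(log(ev)) -
                 0.5 * sum(diag(solve(diag(0.05, 2), C))),
               tolerance = 1e-10)
  # nu = q + 1 kills the log-determinant term
  pr3 <- wishart_prior(nu = 3, scale = 0.05)
  expect_equal(wishart_log_penalty(C, pr3), -0.5 * sum(diag(C)) / 0.05,
               tolerance = 1e-10)
  # scaling identity: penalty(2C) - penalty(C)
  expect_equal(wishart_log_penalty(2 * C, pr) - wishart_log_penalty(C, pr),
               ((4 - 2 - 1) / 2) * 2 * log(2) -
                 0.5 * sum(diag(solve(diag(0.05, 2), C))),
               tolerance = 1e-10)
  expect_error(wishart_log_penalty(matrix(c(1, 2, 2, 1), 2), pr),
               "positive-definite")
})

test_that("flat prior with one cluster reduces to OLS", {
  d <- generate_trial_pair(null_config(7, n = 120))
  d <- d[d$trial == "trial_A", ]
  d$treat <- as.numeric(d$arm == "intervention")
  f <- suppressWarnings(
    fit_mpl_lmm(phq9_post ~ phq9_baseline + treat, d, group = "trial",
                random = ~1, prior = NULL))
  ols <- lm(phq9_post ~ phq9_baseline + treat, d)
  expect_equal(unname(f$fixed_coefs), unname(coef(ols)), tolerance = 1e-6)
})

test_that("per-observation scores sum to zero at the optimum", {
  d <- generate_trial_pair(synthetic_config(seed = 13))
  d$treat <- as.numeric(d$arm == "intervention")
  f <- fit_mpl_lmm(phq9_post ~ trial:phq9_baseline + treat, d,
                   group = "trial", random = ~ 1 + treat)
  expect_true(f$converged)
  expect_true(all(abs(colSums(f$scores)) < 1e-6 * f$n))
  expect_true(all(eigen(f$ranef_cov, TRUE, TRUE)$values > 0))
})

test_that("duplicate clusters shrink tau2 to the prior mode", {
  d <- generate_trial_pair(null_config(17, n = 200))
  d2 <- d
  d2$trial <- factor(ifelse(d$trial == "trial_A", "trial_B", "trial_A"),
                     levels = levels(d$trial))
  both <- rbind(d, d2)   # two trials that are exact copies of each other
  both$treat <- as.numeric(both$arm == "intervention")
  f <- fit_mpl_lmm(phq9_post ~ phq9_baseline + treat, both, group = "trial",
                   random = ~ 1 + treat)
  # penalty-only mode of the relative covariance is (nu - q - 1) * scale =
  # 0.05 I; with no between-trial evidence the estimate cannot exceed it
  # materially
  expect_lt(f$ranef_cov[2, 2] / f$sigma2, 0.05 * 1.5)
  expect_gt(f$ranef_cov[2, 2], 0)
})

test_that("planted between-trial heterogeneity is recovered across many trials", {
  G <- 50; npg <- 200
  est <- vapply(1:100, function(s) {
    set.seed(s)
    g <- factor(rep(seq_len(G), each = npg))
    treat <- rep_len(0:1, G * npg)
    u0 <- rnorm(G, 0, sqrt(0.5)); u1 <- rnorm(G, 0, sqrt(0.48))
    y <- 2 + u0[as.integer(g)] + treat * (-2 + u1[as.integer(g)]) +
      rnorm(G * npg, 0, 4.5)
    df <- data.frame(y, treat, g)
    f <- fit_mpl_lmm(y ~ treat, df, group = "g", random = ~ 1 + treat)
    f$ranef_cov[2, 2]
  }, numeric(1))
  expect_lt(abs(median(est) - 0.48), 0.2 * 0.48)
})

test_that("collinear fixed terms are reported by name", {
  d <- generate_trial_pair(synthetic_config(seed = 19))
  d$treat <- as.numeric(d$arm == "intervention")
  d$dup <- d$phq9_baseline
  expect_error(
    fit_mpl_lmm(phq9_post ~ phq9_baseline + dup + treat, d,
                group = "trial", random = ~1),
    "dup")
})

test_that("CR2 collapses to HC2 with singleton clusters and to 0 on exact fits", {
  d <- generate_trial_pair(synthetic_config(seed = 23))[1:40, ]
  d$treat <- as.numeric(d$arm == "intervention")
  d$cl <- factor(seq_len(40))
  f <- fit_ols_cr2(phq9_post ~ phq9_baseline + treat, d, cluster = "cl")
  X <- model.matrix(~ phq9_baseline + treat, d)
  XtXi <- solve(crossprod(X))
  r <- d$phq9_post - drop(X %*% XtXi %*% crossprod(X, d$phq9_post))
  h <- rowSums((X %*% XtXi) * X)
  hc2 <- sqrt(diag(XtXi %*% crossprod(X * r / sqrt(1 - h)) %*% XtXi))
  expect_equal(unname(f$se), unname(hc2), tolerance = 1e-10)

  d$exact <- 1 + 2 * d$phq9_baseline
  fz <- fit_ols_cr2(exact ~ phq9_baseline, d, cluster = "cl")
  expect_true(all(fz$se < 1e-8))
})

test_that("CR2 errors when a cluster is perfectly fitted by the fixed terms", {
  d <- hand_table()
  d$z <- as.numeric(d$trial == "trial_A") * d$phq9_baseline
  d$cl <- factor(rep(1:2, each = 6))
  d2 <- d[1:7, ]
  d2$cl <- factor(c(rep(1, 6), 2))
  d2$ind <- as.numeric(d2$cl == 2)
  expect_error(fit_ols_cr2(phq9_post ~ ind, d2, cluster = "cl"),
               "perfectly fitted")
})

test_that("lasso path obeys shrinkage limits and BIC selection", {
  d <- generate_trial_pair(synthetic_config(seed = 29))
  mods <- c("pseq", "aqol", "odi", "phq9_baseline")
  grid <- exp(seq(log(20), log(1e-3), length.out = 25))
  lf <- fit_lasso_interactions(d, mods, grid)
  # full shrinkage at the top of the path
  expect_true(all(lf$coef_path[1, lf$penalized] == 0))
  # selected lambda attains the BIC minimum
  expect_equal(lf$bic_path[match(lf$lambda, lf$lambda_grid)],
               min(lf$bic_path))
  # monotone sparsity along decreasing lambda
  nz <- rowSums(lf$coef_path[, lf$penalized, drop = FALSE] != 0)
  expect_true(all(diff(nz) >= 0))
  # lambda = 0 equals unpenalized least squares on the same design
  lf0 <- fit_lasso_interactions(d, mods, 0)
  ols <- lm.fit(lf0$x, lf0$y)$coefficients
  expect_equal(unname(lf0$selected_coefs), unname(ols), tolerance = 1e-4)
  expect_error(fit_lasso_interactions(d, mods, numeric(0)), "empty")
})

test_that("orthogonal standardized design soft-thresholds exactly", {
  set.seed(31)
  n <- 400
  x <- drop(scale(rnorm(n))) / sqrt((n - 1) / n)  # x'x/n = 1
  y <- 2 * x + rnorm(n)
  for (lam in c(0.1, 0.5, 1.5)) {
    b <- mobcate:::cd_lasso(matrix(x, ncol = 1), y, lam, pen = TRUE)
    ols <- sum(x * y) / n
    expect_equal(b, sign(ols) * max(abs(ols) - lam, 0), tolerance = 1e-9)
  }
})

test_that("lasso solution matches glmnet on a shared convention", {
  requireNamespace("glmnet", quietly = TRUE)
  set.seed(37)
  n <- 300; p <- 6
  X <- scale(matrix(rnorm(n * p), n, p))
  X <- sweep(X, 2, sqrt(colMeans(X^2)), "/")       # x'x/n = 1
  y <- drop(X[, 1] * 1.5 - X[, 3] + rnorm(n))
  lam <- 0.25
  mine <- mobcate:::cd_lasso(X, y - mean(y), lam, pen = rep(TRUE, p))
  gn <- glmnet::glmnet(X, y, lambda = lam, standardize = FALSE,
                       intercept = TRUE, thresh = 1e-12)
  expect_equal(unname(mine), unname(as.numeric(gn$beta)), tolerance = 1e-4)
})
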