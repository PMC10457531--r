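# Maximum penalized likelihood ("pseudo-Bayesian") multilevel linear models.
# The Gaussian mixed-model likelihood is augmented with a Wishart log-density
# on the random-effects covariance, so the fit is the posterior mode under a
# weakly informative Wishart prior; boundary (zero-variance) estimates are
# ruled out a priori because the log-determinant term diverges at the
# boundary when nu > q + 1.

#' Wishart prior on the random-effects covariance
#'
#' @param nu degrees of freedom (default 4).
#' @param scale either a positive scalar `s` (expanded to `s * I_q` at fit
#'   time) or a q x q symmetric positive-definite matrix (default 0.05).
#' @return object of class `wishart_prior`.
#' @export
wishart_prior <- function(nu = 4, scale = 0.05) {
  if (is.matrix(scale)) {
    if (!isSymmetric(unname(scale)) || any(eigen(scale, TRUE, TRUE)$values <= 0))
      stop("scale matrix must be symmetric positive-definite")
  } else if (!(is.numeric(scale) && length(scale) == 1 && scale > 0)) {
    stop("scale must be a positive scalar or an SPD matrix")
  }
  structure(list(nu = nu, scale = scale), class = "wishart_prior")
}

prior_scale_matrix <- function(prior, q) {
  S <- prior$scale
  if (!is.matrix(S)) S <- diag(S, q)
  if (nrow(S) != q) stop("prior scale dimension ", nrow(S),
                         " does not match q = ", q)
  if (prior$nu <= q - 1) stop("Wishart prior requires nu > q - 1")
  S
}

#' Log Wishart penalty (unnormalized)
#'
#' Evaluates `((nu - q - 1)/2) * log|cov| - trace(scale^{-1} cov)/2`, the
#' log-density of a Wishart(nu, scale) distribution at `cov` up to its
#' normalizing constant.
#'
#' @param cov symmetric positive-definite q x q matrix.
#' @param prior a [wishart_prior()].
#' @return scalar log penalty.
#' @export
wishart_log_penalty <- function(cov, prior) {
  stopifnot(inherits(prior, "wishart_prior"))
  cov <- as.matrix(cov)
  q <- nrow(cov)
  S <- prior_scale_matrix(prior, q)
  ch <- tryCatch(chol(cov), error = function(e) NULL)
  if (is.null(ch)) stop("cov must be positive-definite")
  logdet <- 2 * sum(log(diag(ch)))
  ((prior$nu - q - 1) / 2) * logdet - 0.5 * sum(diag(solve(S, cov)))
}

# Per-group cross-product summaries; all objective evaluations are O(k^2 q)
# afterwards, independent of n.
mpl_precompute <- function(X, y, Z, g) {
  lev <- levels(g)
  lapply(lev, function(l) {
    i <- which(g == l)
    Xg <- X[i, , drop = FALSE]; Zg <- Z[i, , drop = FALSE]; yg <- y[i]
    list(idx = i, n = length(i),
         XtX = crossprod(Xg), Xty = crossprod(Xg, yg),
         ZtZ = crossprod(Zg), ZtX = crossprod(Zg, Xg),
         Zty = crossprod(Zg, yg), yty = sum(yg^2))
  })
}

# Woodbury pieces for one group given Psi (= ranef_cov / sigma^2).
# Returns X'M^-1X, X'M^-1y, y'M^-1y, log|M| with M = I + Z Psi Z'.
mpl_group_quads <- function(pc, Psi_inv, Psi) {
  A <- Psi_inv + pc$ZtZ                      # q x q
  Ainv <- solve(A)
  XtMX <- pc$XtX - t(pc$ZtX) %*% Ainv %*% pc$ZtX
  XtMy <- pc$Xty - t(pc$ZtX) %*% Ainv %*% pc$Zty
  ytMy <- pc$yty - drop(t(pc$Zty) %*% Ainv %*% pc$Zty)
  # |M| = |I + Z'Z Psi| = |A| * |Psi|
  logdetM <- determinant(A, logarithm = TRUE)$modulus +
    determinant(Psi, logarithm = TRUE)$modulus
  list(XtMX = XtMX, XtMy = XtMy, ytMy = ytMy, logdetM = as.numeric(logdetM))
}

theta_to_L <- function(theta, q) {
  L <- matrix(0, q, q)
  diag(L) <- exp(theta[seq_len(q)])
  if (q > 1) L[lower.tri(L)] <- theta[-seq_len(q)]
  L
}

#' Fit a maximum-penalized-likelihood linear mixed model
#'
#' Maximizes the Gaussian log-likelihood plus [wishart_log_penalty()] on the
#' random-effects covariance over fixed coefficients, the residual variance,
#' and the covariance itself. The covariance is parameterized through the
#' Cholesky factor of `ranef_cov / sigma^2` with log-diagonal, guaranteeing
#' positive-definiteness; beta and sigma^2 are profiled out in closed form, so
#' the numeric search runs over q(q+1)/2 parameters only.
#'
#' @param fixed model formula for the fixed part (outcome on the left).
#' @param data data frame with no missing values in modelled columns.
#' @param group name of the clustering column (the trial).
#' @param random one-sided formula for the random-effects design within
#'   group; default `~1` (random intercept). The canonical analysis model uses
#'   `~ 1 + treat` (trial intercept and trial-specific treatment slope).
#' @param prior a [wishart_prior()], or `NULL` for an unpenalized (flat) fit.
#' @param control list: `maxit` (default 1000), `reltol` (default 1e-10).
#' @param drop_aliased drop collinear fixed-effect columns instead of
#'   erroring (default `FALSE`: collinearity is an error naming the aliased
#'   columns).
#' @return object of class `mpl_fit` with elements `fixed_coefs`, `fixed_se`,
#'   `t`, `p` (Wald, normal reference), `ranef_cov`, `sigma2`,
#'   `penalized_loglik`, `loglik`, `scores` (n x k per-observation score
#'   matrix, columns summing to ~0 at the optimum), `ranef` (per-group BLUPs),
#'   `converged`.
#' @export
fit_mpl_lmm <- function(fixed, data, group, random = ~1,
                        prior = wishart_prior(), control = list(),
                        drop_aliased = FALSE) {
  maxit <- control$maxit %||% 1000
  reltol <- control$reltol %||% 1e-10
  mf <- droplevels(stats::model.frame(fixed, data))
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  if (anyNA(y) || anyNA(X)) stop("missing values in modelled columns")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    if (drop_aliased) {
      X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
    } else {
      aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
      stop("collinear fixed terms: ", paste(aliased, collapse = ", "))
    }
  }
  g <- droplevels(as.factor(data[[group]]))
  if (nlevels(g) < 2 && !is.null(prior))
    warning("fewer than 2 groups: random-effect variances are weakly ",
            "identified and shrink to the prior mode")
  Z <- stats::model.matrix(random, data)
  n <- length(y); k <- ncol(X); q <- ncol(Z)
  S <- if (is.null(prior)) NULL else prior_scale_matrix(prior, q)
  Sinv <- if (is.null(S)) NULL else solve(S)
  nu <- if (is.null(prior)) NA_real_ else prior$nu
  pc <- mpl_precompute(X, y, Z, g)

  profile_eval <- function(theta) {
    L <- theta_to_L(theta, q)
    Psi <- L %*% t(L)
    Psi_inv <- chol2inv(chol(Psi))
    XtMX <- matrix(0, k, k); XtMy <- numeric(k); ytMy <- 0; logdetM <- 0
    for (p_ in pc) {
      gq <- mpl_group_quads(p_, Psi_inv, Psi)
      XtMX <- XtMX + gq$XtMX; XtMy <- XtMy + gq$XtMy
      ytMy <- ytMy + gq$ytMy; logdetM <- logdetM + gq$logdetM
    }
    beta <- solve(XtMX, XtMy)
    rss <- max(ytMy - 2 * sum(beta * XtMy) + drop(t(beta) %*% XtMX %*% beta),
               1e-12)
    sigma2 <- rss / n
    # the Wishart prior acts on the relative covariance Psi = Sigma / sigma^2
    # (the residual-scaled parameterization): this is what keeps it weakly
    # informative across outcomes of any scale while still barring |Psi| -> 0
    pen <- if (is.null(prior)) 0 else {
      ldPsi <- as.numeric(determinant(Psi, TRUE)$modulus)
      ((nu - q - 1) / 2) * ldPsi - 0.5 * sum(Sinv * Psi)
    }
    ll <- -0.5 * n * log(2 * pi) - 0.5 * n * log(sigma2) - 0.5 * logdetM -
      rss / (2 * sigma2)
    list(obj = ll + pen, loglik = ll, beta = beta, sigma2 = sigma2,
         Psi = Psi, Psi_inv = Psi_inv, XtMX = XtMX, rss = rss)
  }

  theta0 <- c(rep(log(0.3), q), rep(0, q * (q - 1) / 2))
  negobj <- function(th) {
    v <- tryCatch(profile_eval(th)$obj, error = function(e) NA_real_)
    if (!is.finite(v)) 1e10 else -v
  }
  if (length(theta0) == 1L) {
    opt <- stats::optim(theta0, negobj, method = "Brent",
                        lower = -20, upper = 10)
  } else {
    opt <- stats::optim(theta0, negobj, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = reltol))
    # restart once from the incumbent to escape premature simplex collapse
    opt2 <- stats::optim(opt$par, negobj, method = "Nelder-Mead",
                         control = list(maxit = maxit, reltol = reltol))
    if (opt2$value < opt$value) opt <- opt2
  }
  sol <- profile_eval(opt$par)
  beta <- drop(sol$beta); names(beta) <- colnames(X)
  # residual-df correction of the ML variance for Wald standard errors
  vc <- sol$sigma2 * n / max(n - ncol(X), 1) * solve(sol$XtMX)
  se <- sqrt(diag(vc)); names(se) <- colnames(X)
  tval <- beta / se
  pval <- 2 * stats::pnorm(-abs(tval))

  # per-observation scores wrt beta: x_i * (V^-1 r)_i
  r <- y - X %*% sol$beta
  w <- numeric(n)
  ranef <- matrix(0, length(pc), q,
                  dimnames = list(levels(g), colnames(Z)))
  for (j in seq_along(pc)) {
    p_ <- pc[[j]]; i <- p_$idx
    Ainv <- solve(sol$Psi_inv + p_$ZtZ)
    Ztr <- crossprod(Z[i, , drop = FALSE], r[i])
    w[i] <- (r[i] - Z[i, , drop = FALSE] %*% (Ainv %*% Ztr)) / sol$sigma2
    ranef[j, ] <- sol$Psi %*% (Ztr - p_$ZtZ %*% Ainv %*% Ztr)
  }
  scores <- X * w

  structure(list(
    fixed_coefs = beta, fixed_se = se, t = tval, p = pval, vcov = vc,
    ranef_cov = sol$sigma2 * sol$Psi, sigma2 = sol$sigma2,
    penalized_loglik = sol$obj, loglik = sol$loglik,
    scores = scores, ranef = ranef, converged = opt$convergence == 0,
    group = group, random = random, prior = prior,
    X = X, Z = Z, g = g, n = n
  ), class = "mpl_fit")
}

#' @export
print.mpl_fit <- function(x, ...) {
  cat("Maximum penalized likelihood linear mixed model\n")
  cat(sprintf("  groups: %d (%s)   n = %d   converged: %s\n",
              nlevels(x$g), x$group, x$n, x$converged))
  tab <- cbind(Estimate = x$fixed_coefs, `Std. Error` = x$fixed_se,
               t = x$t, `p` = x$p)
  print(round(tab, 4))
  cat("Random-effects covariance (tau^2 on the diagonal):\n")
  print(round(x$ranef_cov, 4))
  invisible(x)
}

#' Predicted random-effect contribution per observation
#'
#' @param fit an `mpl_fit`.
#' @return numeric vector `Z_i b_hat[group(i)]` of length n.
#' @export
ranef_contribution <- function(fit) {
  stopifnot(inherits(fit, "mpl_fit"))
  rowSums(fit$Z * fit$ranef[as.character(fit$g), , drop = FALSE])
}
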