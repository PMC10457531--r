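# OLS with bias-reduced linearization (CR2) cluster-robust variance and
# Bell-McCaffrey Satterthwaite degrees of freedom. Used as the sensitivity
# engine for treatment-moderator interaction tests with very few clusters.

#' OLS with CR2 cluster-robust standard errors
#'
#' Point estimates by ordinary least squares; the variance of each coefficient
#' by the CR2 estimator, which rescales each cluster's residuals by the
#' symmetric inverse square root of `I - H_gg` (the within-cluster block of
#' the hat matrix) so that the estimator is exactly unbiased under
#' homoskedasticity. Degrees of freedom for each coefficient are
#' Satterthwaite approximations computed from the same adjustment
#' (Bell-McCaffrey), which is what makes the test usable with as few as two
#' clusters.
#'
#' @param formula model formula.
#' @param data data frame.
#' @param cluster name of the clustering column.
#' @return object of class `ols_cr2` with `coef`, `se`, `df`, `t`, `p`,
#'   `vcov`, `n_clusters`.
#' @export
fit_ols_cr2 <- function(formula, data, cluster) {
  mf <- droplevels(stats::model.frame(formula, data))
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  g <- droplevels(as.factor(data[[cluster]]))
  if (nlevels(g) < 2) stop("need at least 2 clusters")
  n <- nrow(X); k <- ncol(X)
  XtXinv <- chol2inv(qr.R(qr(X)))
  beta <- drop(XtXinv %*% crossprod(X, y)); names(beta) <- colnames(X)
  res <- y - drop(X %*% beta)

  lev <- levels(g)
  # CR2 half-meat per cluster: q_g = (X'X)^-1 X_g' A_g u_g with
  # A_g = (I - H_gg)^{-1/2}.
  meat <- matrix(0, k, k)
  adj <- vector("list", length(lev))
  for (j in seq_along(lev)) {
    i <- which(g == lev[j])
    Xg <- X[i, , drop = FALSE]
    Hgg <- Xg %*% XtXinv %*% t(Xg)
    IH <- diag(length(i)) - Hgg
    ev <- eigen((IH + t(IH)) / 2, symmetric = TRUE)
    # directions absorbed by cluster-constant fixed effects (e.g. stratified
    # trial intercepts) make I - H_gg singular; use the Moore-Penrose inverse
    # square root there, as in the bias-reduced linearization literature
    vals <- ev$values
    if (all(vals < 1e-10))
      stop("cluster '", lev[j], "' is perfectly fitted by the fixed terms; ",
           "the CR2 adjustment is undefined - drop or merge clusters")
    inv <- ifelse(vals > 1e-10, 1 / sqrt(pmax(vals, 0)), 0)
    Ag <- ev$vectors %*% (inv * t(ev$vectors))
    adj[[j]] <- list(idx = i, AX = Ag %*% Xg)
    u <- Ag %*% res[i]
    s <- crossprod(Xg, u)                    # X_g' A_g u_g
    meat <- meat + s %*% t(s)
  }
  V <- XtXinv %*% meat %*% XtXinv
  se <- sqrt(pmax(diag(V), 0)); names(se) <- colnames(X)

  # Bell-McCaffrey Satterthwaite df per coefficient: the CR2 variance for
  # contrast e_j is a quadratic form u' M u; under iid errors
  # df = tr(M Om)^2 / tr((M Om)^2) with Om = I - H, computed via the n x G
  # matrix of cluster "loading" vectors a_g = (I - H)' P_g.
  H_rows <- X %*% XtXinv                      # n x k, H = H_rows %*% t(X)
  df <- numeric(k)
  for (cidx in seq_len(k)) {
    Amat <- matrix(0, n, length(lev))
    for (j in seq_along(lev)) {
      a <- adj[[j]]
      p_g <- drop(a$AX %*% XtXinv[, cidx])    # length |g|
      full <- numeric(n); full[a$idx] <- p_g
      # a_g = (I - H)' P_g = P_g - X (X'X)^-1 X' P_g
      Amat[, j] <- full - drop(H_rows %*% crossprod(X, full))
    }
    G <- crossprod(Amat)                      # G x G: a_g' a_h
    tr1 <- sum(diag(G)); tr2 <- sum(G^2)
    df[cidx] <- if (tr2 > 0) tr1^2 / tr2 else Inf
  }
  names(df) <- colnames(X)
  tval <- ifelse(se > 0, beta / se, 0)
  pval <- 2 * stats::pt(-abs(tval), df)
  pval[se == 0 & beta == 0] <- 1
  structure(list(coef = beta, se = se, df = df, t = tval, p = pval,
                 vcov = V, residuals = res, n_clusters = nlevels(g)),
            class = "ols_cr2")
}

#' @export
print.ols_cr2 <- function(x, ...) {
  cat("OLS with CR2 cluster-robust variance (", x$n_clusters, " clusters)\n",
      sep = "")
  print(round(cbind(Estimate = x$coef, `CR2 SE` = x$se, df = x$df,
                    t = x$t, p = x$p), 4))
  invisible(x)
}
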