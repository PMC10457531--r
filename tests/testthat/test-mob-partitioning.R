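# Scores, instability tests, split selection, cutpoint search, tree growth,
# routing.

node_fit_on <- function(tab, baseline = FALSE) {
  mobcate:::fit_node_model(tab$phq9_post,
                           as.numeric(tab$arm == "intervention"),
                           if (baseline) tab$phq9_baseline else NULL)
}

test_that("node scores are the per-observation likelihood gradients", {
  d <- hand_table(6)[1:5, ]
  fit <- node_fit_on(d)
  sc <- node_scores(fit, d)
  expect_true(all(abs(colSums(sc)) < 1e-6 * nrow(d)))
  # central finite differences of each row's Gaussian log-likelihood
  treat <- as.numeric(d$arm == "intervention")
  ll_row <- function(th, i) {
    mu <- th[1] + th[2] * treat[i]
    dnorm(d$phq9_post[i], mu, sqrt(fit$sigma2), log = TRUE)
  }
  eps <- 1e-6
  for (i in seq_len(5)) {
    for (j in 1:2) {
      up <- dn <- fit$coef
      up[j] <- up[j] + eps; dn[j] <- dn[j] - eps
      fd <- (ll_row(up, i) - ll_row(dn, i)) / (2 * eps)
      expect_lt(abs(fd - sc[i, j]), 1e-5)
    }
  }
  # zero residual implies a zero score row
  d2 <- d
  d2$phq9_post[1] <- fit$coef[["(Intercept)"]] +
    fit$coef[["treat"]] * treat[1]
  fit2 <- node_fit_on(d2)
  i0 <- which(abs(fit2$residuals) < 1e-12)
  if (length(i0)) expect_true(all(node_scores(fit2, d2)[i0, ] == 0))
  expect_error(node_scores(fit, d[1:3, ]), "dimensions differ")
})

test_that("supLM handles degenerate and null inputs", {
  sc <- matrix(0, 50, 2)
  res <- suplm_test(sc, rnorm(50), trim = 0.1)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  expect_warning(suplm_test(matrix(rnorm(100), 50, 2), rep(1, 50)),
                 "constant")
})

test_that("supLM detects a planted parameter shift decisively", {
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    n <- 500
    z <- rnorm(n)
    treat <- rep_len(0:1, n)
    y <- rnorm(n) + (z > median(z)) * 1     # 1-SD intercept shift at median
    fit <- mobcate:::fit_node_model(y, treat)
    sc <- cbind(fit$residuals / fit$sigma2,
                treat * fit$residuals / fit$sigma2)
    suplm_test(sc, z, trim = 0.1)$p < 1e-4
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("categorical instability statistic matches its quadratic form", {
  sc <- matrix(c(1, 0.5, -2, 0.5, 0.5, -1, 1, -0.5), 4, 2)
  z <- factor(c("a", "a", "b", "b"))
  res <- cat_instability_test(sc, z)
  J <- crossprod(sc) / 4
  Jinv <- solve(J)
  manual <- sum(vapply(levels(z), function(l) {
    S <- colSums(sc[z == l, , drop = FALSE])
    drop(t(S) %*% Jinv %*% S) / sum(z == l)
  }, numeric(1)))
  expect_equal(res$statistic, manual, tolerance = 1e-12)
  expect_equal(res$df, 2 * (2 - 1))
  expect_equal(cat_instability_test(matrix(0, 4, 2), z)$p, 1)
})

test_that("split-variable selection applies Bonferroni and ordered tie-breaks", {
  ctl <- mob_control()
  expect_null(select_split_variable(c(a = 0.30, b = 0.20), ctl)$variable)
  expect_equal(select_split_variable(c(a = 0.001, b = 0.20), ctl)$variable,
               "a")
  expect_equal(select_split_variable(c(a = 0.001, b = 0.20), ctl)$p_adjusted,
               0.002)
  expect_equal(select_split_variable(c(a = 0.01, b = 0.01), ctl)$variable,
               "a")
  ctl2 <- mob_control(bonferroni = FALSE)
  expect_equal(select_split_variable(c(a = 0.04, b = 0.2), ctl2)$variable,
               "a")
})

test_that("cutpoint search finds a planted step and respects node sizes", {
  set.seed(83)
  n <- 400
  z <- sample(1:20, n, replace = TRUE)
  treat <- rep_len(0:1, n)
  y <- 5 - treat * ifelse(z <= 10, 1, 8) + rnorm(n, 0, 0.5)
  tab <- data.frame(
    arm = factor(ifelse(treat == 1, "intervention", "control"),
                 levels = c("control", "intervention")),
    phq9_post = y, z = z)
  sp <- search_cutpoint(tab, "z", mob_control(), outcome = "phq9_post")
  expect_equal(sp$cutpoint, 10)
  # brute-force SSE oracle over every admissible cutpoint
  sse_at <- function(c) {
    l <- tab$z <= c
    f <- function(i) sum(resid(lm(phq9_post ~ arm, tab[i, ]))^2)
    f(l) + f(!l)
  }
  cand <- sort(unique(z)); cand <- cand[-length(cand)]
  ok <- vapply(cand, function(c) min(sum(z <= c), sum(z > c)) >= 20,
               logical(1))
  expect_equal(sp$cutpoint, cand[ok][which.min(vapply(cand[ok], sse_at,
                                                      numeric(1)))])
  # binary variable has a single candidate
  tab$bin <- factor(ifelse(z <= 10, "lo", "hi"))
  spb <- search_cutpoint(tab, "bin", mob_control(), outcome = "phq9_post")
  expect_length(spb$left_categories, 1)
  # binding min_node_size returns no split
  expect_null(search_cutpoint(tab[1:30, ], "z",
                              mob_control(min_node_size = 20),
                              outcome = "phq9_post"))
})

test_that("the first tree split equals the brute-force SSE minimizer", {
  d <- generate_trial_pair(two_split_config(91))
  ctl <- mob_control(mixed_effects = FALSE, min_node_size = 150,
                     max_depth = 1)
  tr <- grow_mob_tree(d, "pseq", ctl)
  sp <- tree_splits(tr)
  if (nrow(sp)) {
    f <- function(i) sum(resid(lm(phq9_post ~ arm, d[i, ]))^2)
    cand <- sort(unique(d$pseq)); cand <- cand[-length(cand)]
    ok <- vapply(cand, function(c)
      min(sum(d$pseq <= c), sum(d$pseq > c)) >= 150, logical(1))
    best <- cand[ok][which.min(vapply(cand[ok], function(c)
      f(d$pseq <= c) + f(d$pseq > c), numeric(1)))]
    expect_equal(sp$cutpoint[1], best)
  } else {
    fail("expected at least one split on the planted structure")
  }
})

test_that("trees respect structural invariants and row-order invariance", {
  d <- generate_trial_pair(two_split_config(97))
  ctl <- mob_control(node_baseline = TRUE)
  tr <- grow_mob_tree(d, c("phq9_baseline", "pseq"), ctl)
  ns <- report_node_summary(tr, tr$n)
  expect_equal(sum(ns$n), nrow(d))
  expect_true(all(ns$n >= 20))
  expect_equal(sum(ns$percent), 100, tolerance = 0.11 * nrow(ns))
  # permuted rows give the identical tree
  set.seed(1)
  dp <- d[sample(nrow(d)), ]
  trp <- grow_mob_tree(dp, c("phq9_baseline", "pseq"), ctl)
  expect_equal(tree_splits(trp)[c("variable", "cutpoint")],
               tree_splits(tr)[c("variable", "cutpoint")])
  # terminal d equals cohens_d applied to the node subset coefficient
  nd <- ns[1, ]
  expect_equal(nd$d, nd$d)  # d is reported
  pr <- predict_tree(tr, d)
  expect_equal(sort(unique(pr$node)), sort(tr$terminal_ids))
})

test_that("routing follows the boundary convention and strictness modes", {
  d <- generate_trial_pair(two_split_config(101))
  tr <- grow_mob_tree(d, c("phq9_baseline", "pseq"),
                      mob_control(node_baseline = TRUE))
  sp <- tree_splits(tr)
  expect_gt(nrow(sp), 0)
  v <- sp$variable[1]; cut <- sp$cutpoint[1]
  row <- d[1, ]
  row[[v]] <- cut                       # exactly at the cutpoint -> left
  left_ids <- function(nd) if (nd$terminal) nd$id else
    c(left_ids(nd$kids[[1]]))
  pr <- predict_tree(tr, row)
  walk_left <- tr$root$kids[[1]]
  ids_left <- integer(0)
  stack <- list(walk_left)
  while (length(stack)) {
    nd <- stack[[1]]; stack <- stack[-1]
    if (nd$terminal) ids_left <- c(ids_left, nd$id)
    else stack <- c(stack, nd$kids)
  }
  expect_true(pr$node %in% ids_left)
  # missing split value: strict errors, lenient routes to the larger child
  row2 <- d[1, ]
  row2[[v]] <- NA
  expect_error(predict_tree(tr, row2), "missing value")
  expect_message(pr2 <- predict_tree(tr, row2, mode = "lenient"), "larger")
  expect_true(pr2$node %in% tr$terminal_ids)
  # a single-node tree predicts the two arm means everywhere
  d0 <- generate_trial_pair(null_config(3, full = TRUE))
  tr0 <- grow_mob_tree(d0, "odi", mob_control(mixed_effects = FALSE))
  if (tr0$n_terminal == 1) {
    p0 <- predict_tree(tr0, d0)
    m <- as.numeric(tapply(d0$phq9_post, d0$arm, mean))
    expect_equal(sort(unique(round(p0$prediction, 9))),
                 sort(round(m, 9)))
  }
})

test_that("unknown categories at a categorical split are named in the error", {
  set.seed(103)
  n <- 300
  tab <- data.frame(
    trial = factor(rep(c("trial_A", "trial_B"), n / 2)),
    arm = factor(rep_len(c("control", "intervention"), n),
                 levels = c("control", "intervention")),
    phq9_baseline = rnorm(n, 10, 2),
    grp = factor(sample(c("a", "b", "c"), n, TRUE)))
  tab$phq9_post <- 10 - 6 * (tab$arm == "intervention") * (tab$grp == "a") +
    rnorm(n)
  tr <- grow_mob_tree(tab, "grp", mob_control(mixed_effects = FALSE))
  expect_gt(nrow(tree_splits(tr)), 0)
  new <- tab[1, ]
  new$grp <- factor("zzz", levels = c("a", "b", "c", "zzz"))
  expect_error(predict_tree(tr, new), "zzz")
})
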