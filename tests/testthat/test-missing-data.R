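# Predictor-matrix pruning, multilevel MICE, Rubin pooling, aggregation.

test_that("predictor matrix prunes by pairwise correlation", {
  set.seed(5)
  n <- 400
  target <- rnorm(n)
  strong <- 0.5 * target + rnorm(n, 0, sqrt(1 - 0.25))
  mask <- sample(n, 80)
  obs <- setdiff(seq_len(n), mask)
  # construct the weak column so its pairwise-complete correlation with the
  # target is exactly 0.04 (only observed rows enter that correlation)
  weak <- rnorm(n)
  orth <- residuals(lm(weak[obs] ~ target[obs]))
  weak[obs] <- 0.04 * drop(scale(target[obs])) +
    sqrt(1 - 0.04^2) * drop(scale(orth))
  tab <- data.frame(
    trial = factor(rep(c("trial_A", "trial_B"), each = n / 2)),
    arm = factor(rep(c("control", "intervention"), n / 2)),
    target = target, strong = strong, weak = weak,
    flat = rep(1, n))
  tab$target[mask] <- NA
  expect_warning(P <- build_predictor_matrix(tab, imputation_config()),
                 "constant")
  expect_equal(unname(P["target", "strong"]), 1L)
  expect_equal(unname(P["target", "weak"]), 0L)
  expect_equal(unname(P["target", "flat"]), 0L)
  # structural variables always retained
  expect_equal(unname(P["target", c("trial", "arm")]), c(1L, 1L))
  tab$gone <- NA_real_
  expect_error(suppressWarnings(build_predictor_matrix(tab,
                                                       imputation_config())),
               "zero observed")
})

test_that("a complete table yields m identical copies", {
  d <- generate_trial_pair(synthetic_config(seed = 43, missing_rate = 0))
  st <- impute(d, imputation_config(m = 4, seed = 1))
  expect_length(st$tables, 4)
  for (t in st$tables) expect_identical(t, d)
})

test_that("the default configuration produces a 50-table stack", {
  cfg <- synthetic_config(n_per_trial = c(60, 60), seed = 47)
  dm <- apply_mar_missingness(generate_trial_pair(cfg), cfg)
  st <- impute(dm, imputation_config(seed = 2))
  expect_length(st$tables, 50)
  expect_s3_class(st, "imputed_stack")
})

test_that("imputation preserves observed cells and completes missing ones", {
  cfg <- synthetic_config(seed = 53)
  d <- generate_trial_pair(cfg)
  dm <- apply_mar_missingness(d, cfg)
  obs <- !is.na(dm$phq9_post)
  st <- impute(dm, imputation_config(m = 3, seed = 3))
  for (t in st$tables) {
    expect_false(anyNA(t$phq9_post))
    expect_identical(t$phq9_post[obs], dm$phq9_post[obs])
    expect_true(all(t$phq9_post >= 0 & t$phq9_post <= 27))
  }
  expect_identical(impute(dm, imputation_config(m = 3, seed = 3))$tables,
                   st$tables)
})

test_that("categorical imputation by PMM stays on the observed support", {
  cfg <- synthetic_config(n_per_trial = c(150, 150), seed = 59,
                          missing_rate = 0)
  d <- generate_trial_pair(cfg)
  set.seed(60)
  d$social_support[sample(nrow(d), 40)] <- NA
  st <- impute(d, imputation_config(m = 3, seed = 4))
  expect_equal(st$methods[["social_support"]], "pmm")
  for (t in st$tables) {
    expect_false(anyNA(t$social_support))
    expect_true(all(t$social_support %in% levels(d$social_support)))
  }
})

test_that("imputed arm means recover the full-data truth under MAR", {
  S <- 30
  dif <- matrix(0, S, 2)
  for (i in seq_len(S)) {
    cfg <- synthetic_config(n_per_trial = c(150, 150), seed = i)
    d <- generate_trial_pair(cfg)
    dm <- apply_mar_missingness(d, cfg)
    st <- impute(dm, imputation_config(m = 5, seed = i))
    for (a in 1:2) {
      lvl <- levels(d$arm)[a]
      truth <- mean(d$phq9_post[d$arm == lvl])
      pooled <- mean(vapply(st$tables,
                            function(t) mean(t$phq9_post[t$arm == lvl]),
                            numeric(1)))
      dif[i, a] <- pooled - truth
    }
  }
  mc_se <- apply(dif, 2, sd) / sqrt(S)
  expect_true(all(abs(colMeans(dif)) < 2 * mc_se))
})

test_that("rubin_pool reproduces its closed forms", {
  p0 <- rubin_pool(c(2, 2, 2), c(1, 1, 1))
  expect_equal(p0$estimate, 2)
  expect_equal(p0$between_var, 0)
  expect_equal(p0$se, 1)
  p1 <- rubin_pool(c(1, 2, 3), c(1, 1, 1))
  expect_equal(p1$estimate, 2)
  expect_equal(p1$within_var, 1)
  expect_equal(p1$between_var, 1)
  expect_equal(p1$total_var, 1 + 4 / 3, tolerance = 1e-12)
  expect_equal(p1$se, sqrt(7 / 3), tolerance = 1e-12)
  p2 <- rubin_pool(5, 4)
  expect_equal(p2$estimate, 5)
  expect_equal(p2$se, 2)
  expect_error(rubin_pool(numeric(0), numeric(0)), "no estimates")
  expect_error(rubin_pool(c(1, 2), c(1, -1)), "non-negative")
  # pooling algebra: T >= W always, on random inputs
  set.seed(61)
  for (r in 1:25) {
    est <- rnorm(8); v <- rexp(8)
    p <- rubin_pool(est, v)
    expect_gte(p$total_var, p$within_var)
  }
})

test_that("aggregation takes cell means, modes, and passes observed through", {
  d <- hand_table()
  d$social <- factor(rep(c("yes", "no"), 6), levels = c("no", "yes"))
  miss_num <- c(1, 5); miss_cat <- c(2, 8)
  t1 <- d; t2 <- d; t3 <- d
  t1$phq9_post[miss_num] <- c(8, 20); t2$phq9_post[miss_num] <- c(10, 21)
  t3$phq9_post[miss_num] <- c(12, 22)
  t1$social[miss_cat] <- c("yes", "no"); t2$social[miss_cat] <- c("yes", "no")
  t3$social[miss_cat] <- c("no", "yes")
  st <- structure(list(tables = list(t1, t2, t3),
                       methods = c(phq9_post = "two-level-normal",
                                   social = "pmm"),
                       config = imputation_config(m = 3)),
                  class = "imputed_stack")
  agg <- aggregate_stack(st)
  expect_equal(agg$phq9_post[miss_num], c(10, 21))   # means on the grid
  expect_equal(as.character(agg$social[miss_cat]), c("yes", "no"))  # modes
  expect_identical(agg$phq9_post[-miss_num], d$phq9_post[-miss_num])
  # tie in a 2-of-2 split resolves to the first category order
  t3$social[2] <- "yes"; t2$social[2] <- "no"
  st$tables <- list(t1, t2, t3)  # yes, no, yes -> yes; then force 1-1 tie
  st$tables[[3]]$social[2] <- "no"
  agg2 <- aggregate_stack(structure(list(
    tables = st$tables[c(1, 2)],
    methods = st$methods, config = st$config), class = "imputed_stack"))
  expect_equal(as.character(agg2$social[2]), "no")   # first level on a tie
})
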