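# Internal validation by bootstrap optimism correction and external-trial
# transport validation.

#' Validation configuration
#'
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @param r2_definition `"one_minus_sse_over_sst"` (default) or
#'   `"squared_correlation"` (sensitivity switch).
#' @param stratify_by_trial draw bootstrap resamples within trial strata
#'   (default `FALSE`: participant-level resampling ignoring trial).
#' @return object of class `validation_config`.
#' @export
validation_config <- function(n_boot = 1000L, seed = 1L,
                              r2_definition = c("one_minus_sse_over_sst",
                                                "squared_correlation"),
                              stratify_by_trial = FALSE) {
  r2_definition <- match.arg(r2_definition)
  stopifnot(n_boot >= 1)
  structure(list(n_boot = as.integer(n_boot), seed = as.integer(seed),
                 r2_definition = r2_definition,
                 stratify_by_trial = stratify_by_trial),
            class = "validation_config")
}

#' Proportion of outcome variation explained
#'
#' `1 - SSE/SST` with SST around the observed mean (may be negative for a
#' predictor worse than the mean), or squared Pearson correlation under the
#' sensitivity definition.
#'
#' @param predicted,observed equal-length numeric vectors (n >= 2; observed
#'   non-constant).
#' @param definition see [validation_config()].
#' @return scalar.
#' @export
r_squared <- function(predicted, observed,
                      definition = "one_minus_sse_over_sst") {
  if (length(predicted) != length(observed))
    stop("predicted and observed differ in length")
  if (length(observed) < 2) stop("need at least 2 observations")
  if (stats::sd(observed) == 0) stop("observed vector is constant")
  if (definition == "squared_correlation") {
    if (stats::sd(predicted) == 0) return(0)
    return(stats::cor(predicted, observed)^2)
  }
  1 - sum((observed - predicted)^2) / sum((observed - mean(observed))^2)
}

#' Bootstrap optimism correction of apparent R-squared
#'
#' `fit_procedure(table)` must return a prediction function
#' `function(newdata) -> numeric`, encapsulating the full adaptive pipeline
#' step being validated (e.g. tree growth). Apparent performance is computed
#' by fitting and predicting on the same table; for each bootstrap resample
#' the procedure is refitted and its R-squared on the resample minus its
#' R-squared on the original table estimates the optimism; the mean over
#' resamples is subtracted from the apparent value. Refits that error are
#' excluded and counted; more than 10% failures abort.
#'
#' @param table training table.
#' @param fit_procedure function mapping a table to a prediction function.
#' @param config a [validation_config()].
#' @param outcome outcome column (default `"phq9_post"`).
#' @return object of class `validation_report` with `r2_apparent`,
#'   `optimism`, `r2_adjusted`, `n_boot_used`, `failures`, `config`.
#' @export
bootstrap_bias_correct <- function(table, fit_procedure,
                                   config = validation_config(),
                                   outcome = "phq9_post") {
  y <- table[[outcome]]
  pred_full <- fit_procedure(table)
  r2_app <- r_squared(pred_full(table), y, config$r2_definition)
  draw_idx <- function() {
    if (config$stratify_by_trial) {
      unlist(lapply(split(seq_len(nrow(table)), table$trial), function(i) {
        if (length(i)) sample(i, length(i), replace = TRUE) else integer(0)
      }), use.names = FALSE)
    } else sample.int(nrow(table), nrow(table), replace = TRUE)
  }
  opt <- with_seed(config$seed, {
    vapply(seq_len(config$n_boot), function(b) {
      idx <- draw_idx()
      boot_tab <- table[idx, , drop = FALSE]
      tryCatch({
        pred_b <- fit_procedure(boot_tab)
        r2_boot <- r_squared(pred_b(boot_tab), boot_tab[[outcome]],
                             config$r2_definition)
        r2_orig <- r_squared(pred_b(table), y, config$r2_definition)
        r2_boot - r2_orig
      }, error = function(e) NA_real_)
    }, numeric(1))
  })
  failures <- sum(is.na(opt))
  if (failures > 0.1 * config$n_boot)
    stop("more than 10% of bootstrap refits failed (", failures, " of ",
         config$n_boot, "); the procedure is unstable on resamples")
  optimism <- mean(opt, na.rm = TRUE)
  structure(list(r2_apparent = r2_app, optimism = optimism,
                 r2_adjusted = r2_app - optimism,
                 n_boot_used = config$n_boot - failures,
                 failures = failures, config = config),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "Internal validation (B = %d%s): R2_app = %.3f, optimism = %.3f, R2_adj = %.3f\n",
    x$n_boot_used,
    if (x$failures) sprintf(", %d refit failure(s) excluded", x$failures)
    else "",
    x$r2_apparent, x$optimism, x$r2_adjusted))
  invisible(x)
}

#' External-trial transport validation of a fitted tree
#'
#' Routes the external table through the tree without refitting and returns
#' the R-squared of the terminal-node predictions against the observed
#' post-test outcome.
#'
#' @param tree a `mob_tree`.
#' @param external complete external participant table.
#' @param definition R-squared definition (see [validation_config()]).
#' @return scalar external R-squared.
#' @export
external_validate <- function(tree, external,
                              definition = "one_minus_sse_over_sst") {
  if (anyNA(external$phq9_post))
    stop("external table has missing outcomes; complete it first")
  pr <- predict_tree(tree, external)
  r_squared(pr$prediction, external$phq9_post, definition)
}
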