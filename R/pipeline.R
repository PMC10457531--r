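# End-to-end orchestration: simulate (or load) -> impute -> average treatment
# effect -> univariate moderation -> forest preselection -> tree ->
# validation, with serialized outputs.

#' Pipeline configuration
#'
#' Composite of the stage configurations. The global `seed` re-seeds every
#' stage deterministically (stage seeds are derived offsets), so a pipeline
#' run is reproducible from `(config, seed)` alone.
#'
#' @param synthetic [synthetic_config()] used when no input table is given.
#' @param imputation [imputation_config()].
#' @param mob [mob_control()] for the final tree.
#' @param forest [forest_config()].
#' @param validation [validation_config()].
#' @param rci [rci_config()].
#' @param moderators moderator set (default the 20 canonical names).
#' @param stages character vector of enabled stages, a subset of
#'   `c("impute", "ate", "moderation", "percentile", "forest", "tree",
#'   "validate", "external")`.
#' @param seed global seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            imputation = imputation_config(),
                            mob = mob_control(),
                            forest = forest_config(),
                            validation = validation_config(),
                            rci = rci_config(),
                            moderators = moderator_names(),
                            stages = c("impute", "ate", "moderation",
                                       "percentile", "forest", "tree",
                                       "validate", "external"),
                            seed = 1L) {
  known <- c("impute", "ate", "moderation", "percentile", "forest", "tree",
             "validate", "external")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  structure(list(synthetic = synthetic, imputation = imputation, mob = mob,
                 forest = forest, validation = validation, rci = rci,
                 moderators = moderators, stages = stages,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# Derived analysis column for the univariate stage: multi-level ordinal
# moderators are dichotomized the way the published moderator table reports
# them (education above 13 years; good or very good social support).
uni_moderator_column <- function(table, name) {
  x <- table[[name]]
  if (name == "education")
    factor(ifelse(x == "after_high_school", "yes", "no"), c("no", "yes"))
  else if (name == "social_support")
    factor(ifelse(x %in% c("good", "very_good"), "yes", "no"), c("no", "yes"))
  else x
}

required_columns <- function() {
  c("trial", "arm", moderator_names(), "phq9_post")
}

validate_input_table <- function(table) {
  miss <- setdiff(required_columns(), names(table))
  if (length(miss))
    stop("input table lacks required column(s): ",
         paste(miss, collapse = ", "))
  if (anyNA(table$arm) || anyNA(table$trial))
    stop("arm and trial must be fully observed")
  invisible(table)
}

config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% .Machine$integer.max)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order on synthetic or supplied
#' data and assembles an analysis report. Stage failures abort with the stage
#' name.
#'
#' @param config a [pipeline_config()].
#' @param input_table optional participant table (otherwise synthetic data is
#'   generated from `config$synthetic`).
#' @param external_table optional external-trial table (otherwise generated
#'   when the `external` stage is enabled).
#' @return object of class `analysis_report`.
#' @export
run_pipeline <- function(config = pipeline_config(), input_table = NULL,
                         external_table = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  on <- function(s) s %in% config$stages
  stage <- "data"
  report <- list(provenance = list(
    seed = config$seed, config_hash = config_hash(config),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    package_version = as.character(utils::packageVersion("mobcate"))))
  result <- tryCatch({
    syn <- config$synthetic
    syn$seed <- syn$seed + config$seed
    if (is.null(input_table)) {
      raw <- generate_trial_pair(syn)
      raw <- apply_mar_missingness(raw, syn)
    } else {
      raw <- validate_input_table(input_table)
    }
    report$n <- nrow(raw)
    report$missing_rate <- mean(is.na(raw$phq9_post))

    stage <- "impute"
    stack <- if (on("impute") && anyNA(raw[required_columns()])) {
      ic <- config$imputation
      ic$seed <- ic$seed + config$seed
      impute(raw, ic)
    } else {
      as_imputed_stack(raw[stats::complete.cases(raw[required_columns()]), ])
    }

    if (on("ate")) {
      stage <- "ate"
      report$ate <- estimate_ate(stack)
      report$reliable_change <- reliable_change(stack, config$rci)
    }

    uni <- NULL
    if (on("moderation")) {
      stage <- "moderation"
      uni <- lapply(config$moderators, function(m) {
        ustack <- stack
        ustack$tables <- lapply(ustack$tables, function(t) {
          t[[m]] <- uni_moderator_column(t, m)
          t
        })
        univariate_moderation(ustack, m)
      })
      report$moderator_table <- do.call(rbind, lapply(uni, function(u)
        data.frame(moderator = u$moderator, beta = u$beta_interaction,
                   se = u$se, t = u$t, p = u$p,
                   tau2_intercept = u$tau2_intercept,
                   tau2_slope = u$tau2_slope)))
    }

    if (on("percentile")) {
      stage <- "percentile"
      report$percentile <- percentile_change_analysis(stack, "phq9_baseline")
    }

    stage <- "aggregate"
    agg <- aggregate_stack(stack)

    selected <- config$moderators
    report$preselection <- "skipped"
    if (on("forest")) {
      stage <- "forest"
      fc <- config$forest
      fc$seed <- fc$seed + config$seed
      forest <- grow_forest(agg, config$moderators, fc)
      report$importance <- permutation_importance(forest, agg)
      if (!is.null(uni)) {
        selected <- select_partitioning_variables(report$importance, uni)
        report$preselection <- "importance_or_univariate"
      } else {
        selected <- report$importance$moderator[report$importance$positive]
        report$preselection <- "importance_only"
      }
      if (!length(selected)) selected <- config$moderators
    }
    report$selected_moderators <- selected

    tree <- NULL
    if (on("tree")) {
      stage <- "tree"
      tree <- grow_mob_tree(agg, selected, config$mob, rci = config$rci)
      report$tree <- tree
      report$node_summary <- report_node_summary(tree, nrow(agg))
    }

    if (on("validate") && !is.null(tree)) {
      stage <- "validate"
      vc <- config$validation
      vc$seed <- vc$seed + config$seed
      proc <- function(tab) {
        tr <- grow_mob_tree(tab, selected, config$mob, rci = config$rci)
        function(newdata) predict_tree(tr, newdata)$prediction
      }
      report$validation <- bootstrap_bias_correct(agg, proc, vc)
    }

    if (on("external") && !is.null(tree)) {
      stage <- "external"
      ext <- external_table %||% generate_external_trial(syn)
      report$external <- list(
        n = nrow(ext),
        r2 = external_validate(tree, ext))
      if (!is.null(report$validation))
        report$validation$r2_external <- report$external$r2
    }
    report
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  class(result) <- "analysis_report"
  result
}

#' Terminal-node summary table
#'
#' One row per terminal node with size, share of the sample (one decimal),
#' conditional effect d with CI (two decimals at print time), and
#' reliable-improvement rates per arm as integer percentages with counts.
#'
#' @param tree a `mob_tree`.
#' @param total_n denominator for the percentage (>= sum of node sizes).
#' @return data frame.
#' @export
report_node_summary <- function(tree, total_n) {
  stopifnot(inherits(tree, "mob_tree"))
  rows <- list()
  walk <- function(nd, path) {
    if (!nd$terminal) {
      rule <- if (!is.null(nd$left_categories))
        paste0(nd$split_variable, " in {",
               paste(nd$left_categories, collapse = ","), "}")
      else sprintf("%s <= %g", nd$split_variable, nd$cutpoint)
      walk(nd$kids[[1]], c(path, rule))
      walk(nd$kids[[2]], c(path, paste0("not ", rule)))
      return(invisible())
    }
    imp <- nd$improvement
    rows[[length(rows) + 1L]] <<- data.frame(
      node = nd$id,
      rule = paste(path, collapse = " & "),
      n = nd$n,
      percent = round(100 * nd$n / total_n, 1),
      d = nd$effect$d, ci_low = nd$effect$ci_low, ci_high = nd$effect$ci_high,
      improved_control = sprintf("%d/%d (%d%%)",
                                 imp$improved[1], imp$n[1], imp$percent[1]),
      improved_intervention = sprintf("%d/%d (%d%%)",
                                      imp$improved[2], imp$n[2],
                                      imp$percent[2]),
      improvement_p = nd$improvement_p)
  }
  walk(tree$root, character(0))
  do.call(rbind, rows)
}

#' Printed-proportion arithmetic
#'
#' `round(100 * count / total, digits)` — the rounding convention used for
#' every reported share (one decimal for node percentages, two decimals for
#' baseline characteristics, zero for improvement rates).
#'
#' @param count,total non-negative counts.
#' @param digits decimal places.
#' @return numeric percentage.
#' @export
proportion_percent <- function(count, total, digits = 1) {
  stopifnot(total > 0, count >= 0)
  round(100 * count / total, digits)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Analysis report (seed ", x$provenance$seed, ", config ",
      x$provenance$config_hash, ")\n", sep = "")
  cat(sprintf("  n = %d, missing post-test: %.1f%%\n", x$n,
              100 * x$missing_rate))
  if (!is.null(x$ate)) {
    cat(sprintf("  ATE: beta = %.2f, d = %.2f [%.2f, %.2f]\n",
                x$ate$pooled$estimate, x$ate$effect_size$d,
                x$ate$effect_size$ci_low, x$ate$effect_size$ci_high))
  }
  if (!is.null(x$tree))
    cat(sprintf("  tree: %d terminal node(s)\n", x$tree$n_terminal))
  if (!is.null(x$validation))
    cat(sprintf("  R2_app = %.2f, R2_adj = %.2f%s\n",
                x$validation$r2_apparent, x$validation$r2_adjusted,
                if (!is.null(x$validation$r2_external))
                  sprintf(", external R2 = %.2f", x$validation$r2_external)
                else ""))
  invisible(x)
}

#' Export a tree to Graphviz DOT
#'
#' @param tree a `mob_tree`.
#' @param file optional path; when `NULL` the DOT source is returned.
#' @return DOT source, invisibly when written to file.
#' @export
tree_to_dot <- function(tree, file = NULL) {
  lines <- c("digraph mob_tree {", "  node [shape=box];")
  walk <- function(nd) {
    if (nd$terminal) {
      lines <<- c(lines, sprintf(
        "  n%d [label=\"n = %d (%.1f%%)\\nd = %.2f [%.2f, %.2f]\"];",
        nd$id, nd$n, nd$percent_of_sample, nd$effect$d,
        nd$effect$ci_low, nd$effect$ci_high))
      return(invisible())
    }
    rule <- if (!is.null(nd$left_categories))
      paste0(nd$split_variable, " in {",
             paste(nd$left_categories, collapse = ","), "}")
    else sprintf("%s <= %g", nd$split_variable, nd$cutpoint)
    lines <<- c(lines, sprintf("  n%d [label=\"%s\\nadj. p = %.3g\"];",
                               nd$id, rule, nd$p_adjusted))
    for (kid in nd$kids) {
      lines <<- c(lines, sprintf("  n%d -> n%d;", nd$id, kid$id))
      walk(kid)
    }
  }
  walk(tree$root)
  lines <- c(lines, "}")
  dot <- paste(lines, collapse = "\n")
  if (!is.null(file)) {
    writeLines(dot, file)
    return(invisible(dot))
  }
  dot
}

#' Write an analysis report to disk
#'
#' CSV for tables, JSON for the full report, DOT for the tree.
#'
#' @param report an `analysis_report`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  js <- list(provenance = report$provenance, n = report$n,
             missing_rate = report$missing_rate)
  if (!is.null(report$ate))
    js$ate <- list(beta = report$ate$pooled$estimate,
                   se = report$ate$pooled$se,
                   d = report$ate$effect_size$d,
                   ci = c(report$ate$effect_size$ci_low,
                          report$ate$effect_size$ci_high),
                   tau2_intercept = report$ate$tau2_intercept,
                   tau2_slope = report$ate$tau2_slope)
  if (!is.null(report$reliable_change))
    js$reliable_change <- report$reliable_change$by_arm
  if (!is.null(report$moderator_table)) {
    p <- file.path(dir, "moderator_table.csv")
    utils::write.csv(report$moderator_table, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(report$importance)) {
    p <- file.path(dir, "importance.csv")
    utils::write.csv(report$importance, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(report$node_summary)) {
    p <- file.path(dir, "node_summary.csv")
    utils::write.csv(report$node_summary, p, row.names = FALSE)
    paths <- c(paths, p)
    js$node_summary <- report$node_summary
  }
  if (!is.null(report$tree)) {
    p <- file.path(dir, "tree.dot")
    tree_to_dot(report$tree, p)
    paths <- c(paths, p)
    js$tree_splits <- tree_splits(report$tree)
  }
  if (!is.null(report$validation))
    js$validation <- list(r2_apparent = report$validation$r2_apparent,
                          optimism = report$validation$optimism,
                          r2_adjusted = report$validation$r2_adjusted,
                          r2_external = report$validation$r2_external,
                          n_boot = report$validation$n_boot_used)
  jp <- file.path(dir, "report.json")
  jsonlite::write_json(js, jp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, jp)
  invisible(paths)
}
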