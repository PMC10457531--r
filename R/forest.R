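# Model-based random forest: an ensemble of MOB trees on bootstrap resamples
# with random candidate-variable subsets, used for permutation variable
# importance and predictor preselection ahead of the final tree.

#' Forest configuration
#'
#' @param n_trees number of trees (default 300).
#' @param mtry_fraction fraction of moderators drawn as candidate split
#'   variables per tree (default 1/3, rounded up).
#' @param subsample `"bootstrap"` (with replacement, default) or
#'   `"subsample"` (0.632 n without replacement); out-of-bag rows are tracked
#'   either way.
#' @param control [mob_control()] for the member trees; forests run with
#'   `mixed_effects = FALSE` on the aggregated table.
#' @param seed integer seed; the forest is deterministic given it.
#' @return object of class `forest_config`.
#' @export
forest_config <- function(n_trees = 300L, mtry_fraction = 1 / 3,
                          subsample = c("bootstrap", "subsample"),
                          control = mob_control(mixed_effects = FALSE),
                          seed = 1L) {
  subsample <- match.arg(subsample)
  stopifnot(n_trees >= 1, mtry_fraction > 0, mtry_fraction <= 1)
  structure(list(n_trees = as.integer(n_trees),
                 mtry_fraction = mtry_fraction, subsample = subsample,
                 control = control, seed = as.integer(seed)),
            class = "forest_config")
}

#' Grow a model-based random forest
#'
#' Each tree is grown on a resample of the table with a random subset of
#' `ceiling(mtry_fraction * length(moderators))` candidate partitioning
#' variables; out-of-bag row indices and per-tree permutation seeds are
#' stored for [permutation_importance()].
#'
#' @param table complete participant table.
#' @param moderators candidate moderator columns.
#' @param config a [forest_config()].
#' @return object of class `mob_forest`.
#' @export
grow_forest <- function(table, moderators, config = forest_config()) {
  stopifnot(inherits(config, "forest_config"))
  if (anyNA(table[moderators]) || anyNA(table$phq9_post))
    stop("forest requires a complete table; aggregate or impute first")
  n <- nrow(table)
  mtry <- ceiling(config$mtry_fraction * length(moderators))
  with_seed(config$seed, {
    trees <- vector("list", config$n_trees)
    for (b in seq_len(config$n_trees)) {
      idx <- if (config$subsample == "bootstrap")
        sample.int(n, n, replace = TRUE)
      else sample.int(n, ceiling(0.632 * n))
      oob <- setdiff(seq_len(n), unique(idx))
      cand <- sample(moderators, mtry)
      tree <- grow_mob_tree(table[idx, , drop = FALSE], cand,
                            control = config$control)
      trees[[b]] <- list(tree = tree, oob = oob, candidates = cand,
                         perm_seed = sample.int(.Machine$integer.max, 1))
    }
    structure(list(trees = trees, moderators = moderators, config = config,
                   n = n,
                   fingerprint = table_fingerprint(table, "phq9_post")),
              class = "mob_forest")
  })
}

#' @export
print.mob_forest <- function(x, ...) {
  sizes <- vapply(x$trees, function(t) t$tree$n_terminal, integer(1))
  cat(sprintf("Model-based forest: %d trees (mtry %d of %d moderators), %s resampling\n",
              length(x$trees),
              ceiling(x$config$mtry_fraction * length(x$moderators)),
              length(x$moderators), x$config$subsample))
  cat(sprintf("  terminal nodes per tree: median %g (range %d-%d)\n",
              stats::median(sizes), min(sizes), max(sizes)))
  invisible(x)
}

# Gaussian negative log-likelihood of rows under a tree's terminal models.
tree_oob_nll <- function(tree, table) {
  pr <- predict_tree(tree, table)
  # collect per-terminal sigma2 once
  sigmap <- new.env(parent = emptyenv())
  walk <- function(nd) {
    if (nd$terminal) assign(as.character(nd$id), nd$fit$sigma2, sigmap)
    else { walk(nd$kids[[1]]); walk(nd$kids[[2]]) }
  }
  walk(tree$root)
  s2 <- vapply(as.character(pr$node), function(k) get(k, sigmap), numeric(1))
  -sum(stats::dnorm(table$phq9_post, pr$prediction, sqrt(s2), log = TRUE))
}

#' Out-of-bag permutation variable importance
#'
#' For each moderator and each tree in which it was a candidate, evaluates
#' the out-of-bag negative log-likelihood of the tree's node models before
#' and after permuting the moderator's out-of-bag values (one permutation per
#' tree, seeded at forest growth); importance is the mean per-observation
#' increase. Negative values are possible and preserved; a moderator never
#' used in any split has importance exactly 0.
#'
#' @param forest a `mob_forest`.
#' @param table the table the forest was grown on.
#' @return data frame (`importance_table`) with `moderator`, `importance`,
#'   `n_trees` (trees where it was a candidate), `positive` flag.
#' @export
permutation_importance <- function(forest, table) {
  stopifnot(inherits(forest, "mob_forest"))
  if (!identical(forest$fingerprint, table_fingerprint(table, "phq9_post")))
    stop("table does not match the one the forest was grown on")
  acc <- stats::setNames(numeric(length(forest$moderators)),
                         forest$moderators)
  cnt <- stats::setNames(integer(length(forest$moderators)),
                         forest$moderators)
  for (tr in forest$trees) {
    oob <- tr$oob
    if (!length(oob)) next
    oob_tab <- table[oob, , drop = FALSE]
    base_nll <- tree_oob_nll(tr$tree, oob_tab)
    used <- unique(tree_splits(tr$tree)$variable)
    with_seed(tr$perm_seed, {
      for (v in tr$candidates) {
        if (!(v %in% used)) {
          cnt[v] <- cnt[v] + 1L        # permuting cannot change predictions
          next
        }
        perm_tab <- oob_tab
        perm_tab[[v]] <- sample(perm_tab[[v]])
        nll <- tree_oob_nll(tr$tree, perm_tab)
        acc[v] <- acc[v] + (nll - base_nll) / length(oob)
        cnt[v] <- cnt[v] + 1L
      }
    })
  }
  imp <- ifelse(cnt > 0, acc / pmax(cnt, 1L), 0)
  out <- data.frame(moderator = forest$moderators, importance = imp,
                    n_trees = as.integer(cnt), positive = imp > 0,
                    row.names = NULL)
  class(out) <- c("importance_table", class(out))
  out
}

#' Preselect partitioning variables
#'
#' Implements the selection rule for the final tree: a moderator is retained
#' if its forest permutation importance is positive and/or its univariate
#' interaction test is significant at the 5% level.
#'
#' @param importance an `importance_table` from [permutation_importance()].
#' @param univariate list of `moderator_result` objects covering the same
#'   moderators.
#' @param alpha significance threshold for the univariate route (default
#'   0.05).
#' @return character vector of selected moderators (declared order).
#' @export
select_partitioning_variables <- function(importance, univariate,
                                          alpha = 0.05) {
  uni_names <- vapply(univariate, `[[`, character(1), "moderator")
  if (!setequal(importance$moderator, uni_names)) {
    miss <- c(setdiff(importance$moderator, uni_names),
              setdiff(uni_names, importance$moderator))
    stop("moderator sets differ between importance and univariate results: ",
         paste(unique(miss), collapse = ", "))
  }
  uni_p <- stats::setNames(vapply(univariate, `[[`, numeric(1), "p"),
                           uni_names)
  keep <- importance$importance > 0 |
    uni_p[importance$moderator] < alpha
  importance$moderator[keep]
}
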