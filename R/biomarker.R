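# Random-forest biomarker discovery: taxon abundances regressed against
# continuous-monocropping years (or classified by group), permutation
# importance ranking, and cross-validated recursive feature elimination to
# pick a minimal biomarker set.

#' Fit a random-forest model of cropping years on taxon abundances
#'
#' @param rel a `rel_abund`, typically aggregated to one taxonomic rank.
#' @param target numeric vector (regression: monocropping years per sample)
#'   or factor (classification); one value per sample, in row order.
#' @param task `"regression"` or `"classification"`.
#' @param n_trees number of trees (default 500).
#' @param seed RNG seed.
#' @return list of class `rf_biomarker`: `model` (the randomForest fit),
#'   `task`, `variance_explained` (regression, out-of-bag
#'   \eqn{1 - MSE_{oob}/Var(y)}) or `oob_accuracy`, `importance` (named,
#'   sorted decreasing; permutation importance), `impurity_importance`,
#'   `zero_variance_taxa`, `group_means` (taxon x group mean permille),
#'   `seed`, `n_trees`.
#' @export
fit_rf_model <- function(rel, target, task = c("regression",
                                               "classification"),
                         n_trees = 500, seed = 1) {
  task <- match.arg(task)
  if (n_trees < 100) stop("n_trees must be >= 100")
  X <- as.data.frame(rel$values, check.names = FALSE)
  taxa <- colnames(X)
  colnames(X) <- make.names(taxa)               # RF-safe names
  y <- if (task == "regression") as.numeric(target) else as.factor(target)
  if (length(unique(y)) < 2) stop("target needs at least 2 distinct values")
  zero_var <- taxa[apply(rel$values, 2, function(v) stats::var(v) == 0)]
  # regression on a handful of distinct year values is the intended design;
  # randomForest warns about it on every fit
  model <- withr::with_seed(seed, suppressWarnings(
    randomForest::randomForest(X, y, ntree = n_trees, importance = TRUE)))
  type <- if (task == "regression") 1L else 1L   # %IncMSE / MeanDecrAcc
  imp <- randomForest::importance(model, type = type)[, 1]
  imp_gini <- randomForest::importance(model, type = 2L)[, 1]
  names(imp) <- names(imp_gini) <- taxa
  imp[zero_var] <- 0
  imp <- sort(imp, decreasing = TRUE)
  grp <- rel$metadata$group
  group_means <- vapply(unique(grp), function(g)
    colMeans(rel$values[grp == g, , drop = FALSE]),
    numeric(ncol(rel$values)))
  structure(list(
    model = model, task = task,
    variance_explained = if (task == "regression")
      1 - utils::tail(model$mse, 1) / mean((y - mean(y))^2) else NULL,
    oob_accuracy = if (task == "classification")
      1 - utils::tail(model$err.rate[, "OOB"], 1) else NULL,
    importance = imp, impurity_importance = imp_gini,
    zero_variance_taxa = zero_var, group_means = group_means,
    seed = seed, n_trees = n_trees), class = "rf_biomarker")
}

#' Cross-validated feature-number selection (recursive elimination)
#'
#' Ten-fold cross-validation in the style of `randomForest::rfcv()`:
#' features are ranked by importance within the training folds and the CV
#' prediction error is evaluated at feature counts along a halving schedule
#' (all, half, quarter, ..., 1). The curve is averaged over folds and
#' `n_repeats` repetitions, and the biomarker set is the top-ranked features
#' at the count minimizing mean CV error (ties broken toward the smallest
#' count; `rule = "one_se"` instead picks the smallest count within one
#' standard error of the minimum).
#'
#' @param rel a `rel_abund`.
#' @param target as in [fit_rf_model()].
#' @param task `"regression"` or `"classification"`.
#' @param n_folds folds (default 10).
#' @param n_repeats repetitions of the whole CV (default 5).
#' @param n_trees trees per forest (default 500).
#' @param rule `"min"` (default) or `"one_se"`.
#' @param seed RNG seed.
#' @return list of class `rf_cv`: `cv_curve` (data.frame `n_features`,
#'   `mean_error`, `se_error`), `selected_n`, `selected_taxa`, `fit` (the
#'   full-data [fit_rf_model()] result), `rule`, `seed`.
#' @export
cv_feature_selection <- function(rel, target,
                                 task = c("regression", "classification"),
                                 n_folds = 10, n_repeats = 5, n_trees = 500,
                                 rule = c("min", "one_se"), seed = 1) {
  task <- match.arg(task)
  rule <- match.arg(rule)
  if (n_folds > nrow(rel$values))
    stop("n_folds exceeds the number of samples")
  X <- as.data.frame(rel$values, check.names = FALSE)
  taxa <- colnames(X)
  colnames(X) <- make.names(taxa)
  y <- if (task == "regression") as.numeric(target) else as.factor(target)
  runs <- withr::with_seed(seed,
    lapply(seq_len(n_repeats), function(r) suppressWarnings(
      randomForest::rfcv(X, y, cv.fold = n_folds, scale = "log",
                         step = 0.5, ntree = n_trees))))
  counts <- runs[[1]]$n.var                     # decreasing schedule
  errs <- vapply(runs, function(r) r$error.cv, numeric(length(counts)))
  errs <- matrix(errs, nrow = length(counts))
  mean_err <- rowMeans(errs)
  se_err <- apply(errs, 1, stats::sd) / sqrt(max(1, n_repeats))
  ord <- order(counts)                          # ascending for tie-breaks
  sel_idx <- if (rule == "min") {
    ord[which.min(mean_err[ord])]               # smallest count at min
  } else {
    cutoff <- min(mean_err) + se_err[which.min(mean_err)]
    ord[which(mean_err[ord] <= cutoff)[1]]
  }
  selected_n <- counts[sel_idx]
  fit <- fit_rf_model(rel, target, task = task, n_trees = n_trees,
                      seed = seed)
  structure(list(
    cv_curve = data.frame(n_features = counts, mean_error = mean_err,
                          se_error = se_err),
    selected_n = selected_n,
    selected_taxa = names(fit$importance)[seq_len(selected_n)],
    fit = fit, rule = rule, seed = seed), class = "rf_cv")
}

#' Ranked biomarker table
#'
#' @param result an `rf_biomarker` or `rf_cv`.
#' @param top_k number of taxa to report (default 17); clipped with a
#'   warning when it exceeds the available taxa.
#' @return data.frame `rank`, `taxon`, `importance`, plus one mean
#'   relative-abundance column per group (heatmap input).
#' @export
biomarker_report <- function(result, top_k = 17) {
  fit <- if (inherits(result, "rf_cv")) result$fit else result
  imp <- fit$importance
  if (top_k > length(imp)) {
    warning("top_k clipped to ", length(imp), " available taxa")
    top_k <- length(imp)
  }
  taxa <- names(imp)[seq_len(top_k)]
  out <- data.frame(rank = seq_len(top_k), taxon = taxa,
                    importance = unname(imp[seq_len(top_k)]),
                    stringsAsFactors = FALSE)
  gm <- fit$group_means[taxa, , drop = FALSE]
  colnames(gm) <- paste0("mean_permille_", colnames(gm))
  cbind(out, as.data.frame(gm, row.names = NULL))
}
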