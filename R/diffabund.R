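# Wilcoxon rank-sum differential-abundance screening with BH correction.

#' Two-sample Wilcoxon rank-sum test
#'
#' Thin, mode-explicit wrapper around [stats::wilcox.test()]. In `"auto"`
#' mode the exact p-value is enumerated when the combined sample size is at
#' most 12 and there are no ties; otherwise the normal approximation with
#' tie and continuity corrections is used. Two-sided.
#'
#' @param x,y numeric vectors.
#' @param mode `"auto"`, `"exact"` or `"normal_approx"`.
#' @return list with `W` (rank-sum statistic of `x`) and `p_value`.
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("auto", "exact",
                                             "normal_approx")) {
  mode <- match.arg(mode)
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- switch(mode,
    auto = (length(x) + length(y) <= 12) && !ties,
    exact = TRUE,
    normal_approx = FALSE)
  if (exact && ties)
    stop("exact mode is unavailable with ties; use 'normal_approx'")
  if (all(c(x, y) == c(x, y)[1]))
    return(list(W = length(x) * length(y) / 2, p_value = 1))
  ht <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  list(W = unname(ht$statistic), p_value = min(1, ht$p.value))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j},
#' capped at 1 and mapped back to the input order.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return numeric vector of q-values, same order as input.
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Differential-abundance screen between two groups
#'
#' Taxa whose median per-mille relative abundance exceeds
#' `median_threshold_permille` in at least one group (`prefilter = "any"`,
#' default) or in both groups (`"both"`) enter a per-taxon Wilcoxon
#' rank-sum test; BH correction is applied over the tested taxa only, and
#' taxa with `q < alpha` are flagged significant. Log2 fold changes
#' (group_a over group_b) are attached.
#'
#' @param rel a `rel_abund` whose metadata has a `group` column.
#' @param group_a,group_b group labels to compare.
#' @param median_threshold_permille abundance prefilter, in permille
#'   (default 2, i.e. 0.2%).
#' @param alpha FDR level (default 0.05).
#' @param prefilter `"any"` or `"both"` (see above).
#' @param mode Wilcoxon mode passed to [wilcoxon_rank_sum()].
#' @param pseudo pseudo-count for the fold change.
#' @return data.frame of class `diff_abund` with columns `taxon`,
#'   `median_a`, `median_b`, `W`, `p`, `q`, `log2FC`, `significant`;
#'   attributes `groups`, `threshold`, `alpha`, `prefilter`.
#' @export
diff_abund_screen <- function(rel, group_a, group_b,
                              median_threshold_permille = 2, alpha = 0.05,
                              prefilter = c("any", "both"), mode = "auto",
                              pseudo = 0.001) {
  prefilter <- match.arg(prefilter)
  g <- rel$metadata$group
  A <- rel$values[g == group_a, , drop = FALSE]
  B <- rel$values[g == group_b, , drop = FALSE]
  if (nrow(A) < 2 || nrow(B) < 2)
    stop("both groups need at least 2 samples")
  med_a <- apply(A, 2, stats::median)
  med_b <- apply(B, 2, stats::median)
  keep <- if (prefilter == "any")
    med_a > median_threshold_permille | med_b > median_threshold_permille
  else
    med_a > median_threshold_permille & med_b > median_threshold_permille
  out <- data.frame(taxon = character(), median_a = numeric(),
                    median_b = numeric(), W = numeric(), p = numeric(),
                    q = numeric(), log2FC = numeric(),
                    significant = logical(), stringsAsFactors = FALSE)
  if (!any(keep)) {
    warning("no taxon passed the median-abundance prefilter")
  } else {
    taxa <- colnames(rel$values)[keep]
    tests <- lapply(taxa, function(t)
      wilcoxon_rank_sum(A[, t], B[, t], mode = mode))
    p <- vapply(tests, `[[`, numeric(1), "p_value")
    lfc <- log2_fold_change(rel, group_a, group_b, pseudo = pseudo)
    out <- data.frame(
      taxon = taxa,
      median_a = med_a[taxa], median_b = med_b[taxa],
      W = vapply(tests, `[[`, numeric(1), "W"),
      p = p, q = bh_fdr(p), log2FC = lfc[taxa],
      stringsAsFactors = FALSE, row.names = NULL)
    out$significant <- out$q < alpha
  }
  structure(out, class = c("diff_abund", "data.frame"),
            groups = c(group_a, group_b),
            threshold = median_threshold_permille, alpha = alpha,
            prefilter = prefilter)
}

#' Write a differential-abundance result as TSV
#' @param result a `diff_abund`.
#' @param path output path.
#' @export
write_diff_abund <- function(result, path) {
  utils::write.table(as.data.frame(result), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(result)
}
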