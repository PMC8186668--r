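# Alpha/beta diversity, ordination and multivariate tests. Standard
# ecological statistics are delegated to vegan/ape; phylogenetic metrics
# (Faith PD, weighted UniFrac) are computed by direct branch accumulation on
# the ape tree structure.

#' Alpha diversity of one or more count/abundance rows
#'
#' @param x numeric vector (one sample) or matrix (samples x taxa).
#' @param metric `"observed_otus"` (richness) or `"shannon"`.
#' @param base logarithm base for Shannon entropy; default 2 (bits).
#' @return numeric scalar or named vector (one value per row).
#' @export
alpha_diversity <- function(x, metric = c("observed_otus", "shannon"),
                            base = 2) {
  metric <- match.arg(metric)
  if (is.matrix(x))
    return(apply(x, 1, alpha_diversity, metric = metric, base = base))
  if (sum(x) <= 0) stop("empty sample: row sum must be positive")
  if (metric == "observed_otus") return(sum(x > 0))
  vegan::diversity(x, index = "shannon") / log(base)
}

#' Faith's phylogenetic diversity
#'
#' Total branch length of the minimal subtree spanning the observed taxa and
#' the root (the stem to the root is included, i.e. the rooted convention;
#' a single observed tip already contributes its full root-to-tip path).
#'
#' @param x numeric vector with taxon names, or samples x taxa matrix.
#' @param tree a rooted `phylo` tree whose tip labels cover the observed
#'   taxa.
#' @return numeric scalar or named vector, in branch-length units.
#' @export
faith_pd <- function(x, tree) {
  if (is.matrix(x)) return(apply(x, 1, faith_pd, tree = tree))
  observed <- names(x)[x > 0]
  missing <- setdiff(observed, tree$tip.label)
  if (length(missing))
    stop("observed OTU(s) missing from tree: ",
         paste(utils::head(missing, 5), collapse = ", "))
  if (!length(observed)) return(0)
  if (any(tree$edge.length < 0)) stop("negative branch length in tree")
  # mark every edge on a path from an observed tip to the root
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- ape::Ntip(tree) + 1L
  keep <- logical(max(tree$edge))
  for (tip in match(observed, tree$tip.label)) {
    v <- tip
    while (v != root && !keep[v]) {
      keep[v] <- TRUE
      v <- parent[v]
    }
  }
  sum(tree$edge.length[keep[tree$edge[, 2]]])
}

#' Rarefaction curves for alpha diversity
#'
#' For each sample and each depth, the metric is averaged over `n_draws`
#' random subsamples drawn without replacement. For `observed_otus` the
#' hypergeometric closed-form expectation
#' \eqn{E[S] = \sum_i (1 - C(N - N_i, d) / C(N, d))} is also reported.
#'
#' @param table an [otu_table].
#' @param depths increasing integer depths; default 10 evenly spaced values
#'   up to the minimum sample depth. Depths exceeding a sample's total are
#'   skipped for that sample with a warning.
#' @param n_draws number of random subsamples per depth (default 10).
#' @param metric `"observed_otus"` or `"shannon"`.
#' @param seed RNG seed.
#' @return list of class `rarefaction_curve` with `depths`, `mean`, `sd`
#'   (samples x depths matrices, NA where skipped), `expected` (closed form,
#'   `observed_otus` only), `metric`, `n_draws`.
#' @export
rarefaction_curve <- function(table, depths = NULL, n_draws = 10,
                              metric = c("observed_otus", "shannon"),
                              seed = 1) {
  metric <- match.arg(metric)
  if (n_draws < 1) stop("n_draws must be >= 1")
  counts <- table$counts
  totals <- rowSums(counts)
  if (is.null(depths))
    depths <- unique(round(seq(1, min(totals), length.out = 10)))
  depths <- sort(unique(as.integer(depths)))
  ns <- nrow(counts)
  mean_m <- sd_m <- exp_m <- matrix(NA_real_, ns, length(depths),
                                    dimnames = list(rownames(counts),
                                                    depths))
  withr::local_seed(seed)
  for (s in seq_len(ns)) {
    row <- counts[s, ]
    pool <- rep.int(seq_along(row), row)
    for (j in seq_along(depths)) {
      d <- depths[j]
      if (d > totals[s]) {
        warning(sprintf("depth %d exceeds total of sample '%s'; skipped",
                        d, rownames(counts)[s]))
        next
      }
      vals <- vapply(seq_len(n_draws), function(i) {
        sub <- tabulate(sample(pool, d), nbins = length(row))
        if (metric == "observed_otus") sum(sub > 0)
        else alpha_diversity(sub, "shannon")
      }, numeric(1))
      mean_m[s, j] <- mean(vals)
      sd_m[s, j] <- stats::sd(vals)
      if (metric == "observed_otus")
        exp_m[s, j] <- suppressWarnings(vegan::rarefy(row, sample = d))
    }
  }
  structure(list(depths = depths, mean = mean_m, sd = sd_m,
                 expected = if (metric == "observed_otus") exp_m else NULL,
                 metric = metric, n_draws = n_draws),
            class = "rarefaction_curve")
}

#' Bray-Curtis dissimilarity
#'
#' @param rel a `rel_abund` (per-mille rows).
#' @return a `dist` object over samples.
#' @export
bray_curtis <- function(rel) {
  vegan::vegdist(rel$values, method = "bray")
}

#' Weighted UniFrac distance
#'
#' Raw weighted UniFrac between communities A and B is
#' \eqn{\sum_b l_b |A_b - B_b|} over branches, where \eqn{A_b} is the
#' fraction of community A descending from branch b; the normalized variant
#' divides by \eqn{\sum_b l_b (A_b + B_b)}.
#'
#' @param rel a `rel_abund`; every taxon must be a tip of `tree`.
#' @param tree rooted `phylo` with non-negative branch lengths.
#' @param normalized divide by the pairwise normalizer (default `TRUE`).
#' @return a `dist` object over samples.
#' @export
weighted_unifrac <- function(rel, tree, normalized = TRUE) {
  if (any(tree$edge.length < 0)) stop("negative branch length in tree")
  taxa <- colnames(rel$values)
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing))
    stop("taxa missing from tree: ",
         paste(utils::head(missing, 5), collapse = ", "))
  P <- rel$values / rowSums(rel$values)        # proportions
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  # per-sample mass under every node, accumulated child -> parent in
  # postorder
  W <- matrix(0, nrow(P), nnode)
  W[, match(taxa, tree$tip.label)] <- P
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  ord <- match(paste(edge[, 1], edge[, 2]),
               paste(tree$edge[, 1], tree$edge[, 2]))
  len <- tree$edge.length[ord]
  for (k in seq_len(nrow(edge)))
    W[, edge[k, 1]] <- W[, edge[k, 1]] + W[, edge[k, 2]]
  B <- W[, edge[, 2], drop = FALSE]            # mass under each branch
  ns <- nrow(P)
  d <- matrix(0, ns, ns, dimnames = list(rownames(P), rownames(P)))
  for (i in seq_len(ns - 1)) for (j in seq((i + 1), ns)) {
    raw <- sum(len * abs(B[i, ] - B[j, ]))
    if (normalized) {
      den <- sum(len * (B[i, ] + B[j, ]))
      raw <- if (den > 0) raw / den else 0
    }
    d[i, j] <- d[j, i] <- raw
  }
  stats::as.dist(d)
}

#' Principal coordinates analysis (classical metric scaling)
#'
#' Double-centers \eqn{-D^2/2} and eigendecomposes it. Axes with eigenvalues
#' above a numerical tolerance are retained; proportions explained are taken
#' over the positive eigenvalues only. Negative eigenvalues (non-Euclidean
#' input) are reported unchanged, not corrected.
#'
#' @param dm a `dist` or symmetric matrix with zero diagonal.
#' @return list of class `ordination` with `coordinates`, `eigenvalues`,
#'   `proportion_explained`.
#' @export
pcoa <- function(dm) {
  if (!inherits(dm, "dist")) {
    m <- as.matrix(dm)
    if (!isSymmetric(unname(m), tol = 1e-8))
      stop("distance matrix must be symmetric")
    dm <- stats::as.dist(m)
  }
  n <- attr(dm, "Size")
  # cmdscale warns when non-Euclidean input yields < k positive
  # eigenvalues; that is the expected case here and is reported via eig
  fit <- suppressWarnings(stats::cmdscale(dm, k = n - 1, eig = TRUE))
  eig <- fit$eig
  tol <- sqrt(.Machine$double.eps) * max(abs(eig), 1)
  pos <- eig > tol
  coords <- fit$points[, seq_len(min(sum(pos), ncol(fit$points))),
                       drop = FALSE]
  if (ncol(coords))
    colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  structure(list(coordinates = coords, eigenvalues = eig,
                 proportion_explained = eig[pos] / sum(eig[pos])),
            class = "ordination")
}

#' PERMANOVA (distance-based multivariate ANOVA)
#'
#' Anderson's permutational MANOVA via [vegan::adonis2()]: the pseudo-F and
#' \eqn{R^2 = SS_{between}/SS_{total}} come from the partition of squared
#' distances, and the p-value is
#' \eqn{(1 + \#\{F_{perm} \ge F_{obs}\}) / (1 + n_{perm})} under label
#' permutation.
#'
#' @param dm a `dist` over samples.
#' @param labels group labels, one per sample (same order as `dm`).
#' @param n_permutations number of permutations (default 999).
#' @param seed RNG seed for the permutation stream.
#' @param strata optional blocking factor restricting permutations.
#' @return list of class `permanova` with `pseudo_F`, `R2`, `p_value`,
#'   `n_permutations`.
#' @export
permanova <- function(dm, labels, n_permutations = 999, seed = 1,
                      strata = NULL) {
  labels <- as.factor(labels)
  sizes <- table(labels)
  if (length(sizes) < 2) stop("need at least 2 groups")
  if (any(sizes < 2))
    stop("group(s) of size 1: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  df <- data.frame(labels = labels)
  perm <- if (is.null(strata)) n_permutations else
    permute::how(blocks = as.factor(strata), nperm = n_permutations)
  fit <- withr::with_seed(seed,
    vegan::adonis2(dm ~ labels, data = df, permutations = perm))
  structure(list(pseudo_F = fit$F[1], R2 = fit$R2[1],
                 p_value = fit$"Pr(>F)"[1],
                 n_permutations = n_permutations),
            class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.3f, R2 = %.3f, p = %.4g (%d perms)\n",
              x$pseudo_F, x$R2, x$p_value, x$n_permutations))
  invisible(x)
}

#' Redundancy analysis of community composition on environmental constraints
#'
#' The (optionally Hellinger-transformed) response is regressed on the
#' z-scored constraints via [vegan::rda()]; constrained axes are the PCA of
#' the fitted values. With `constraints = NULL` this reduces to a plain PCA
#' of the response.
#'
#' @param rel a `rel_abund`.
#' @param constraints data.frame of sample-by-property real covariates
#'   (rownames = sample ids), or `NULL`.
#' @param transform `"hellinger"` (default) or `"none"`.
#' @return list of class `rda_result`: `coordinates` (site scores),
#'   `eigenvalues`, `proportion_explained`, `constrained_proportion`,
#'   `species_scores`, `biplot_scores`, and the underlying vegan `fit`.
#' @export
rda_constrained <- function(rel, constraints = NULL,
                            transform = c("hellinger", "none")) {
  transform <- match.arg(transform)
  Y <- rel$values
  if (transform == "hellinger") Y <- vegan::decostand(Y, "hellinger")
  if (is.null(constraints)) {
    fit <- vegan::rda(Y)
    constrained_prop <- 0
  } else {
    constraints <- as.data.frame(constraints)[rownames(Y), , drop = FALSE]
    if (nrow(Y) <= ncol(constraints))
      stop("need more samples than constraints")
    X <- scale(as.matrix(constraints))
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      dep <- colnames(X)[setdiff(seq_len(ncol(X)),
                                 qrX$pivot[seq_len(qrX$rank)])]
      stop("collinear constraint column(s): ", paste(dep, collapse = ", "))
    }
    df <- as.data.frame(X)
    fit <- vegan::rda(Y ~ ., data = df)
    constrained_prop <- fit$CCA$tot.chi / fit$tot.chi
  }
  total_rank <- sum(c(fit$CCA$rank, fit$CA$rank))
  # vegan chats when the constrained fit leaves no residual component
  sc <- suppressMessages(suppressWarnings(
    vegan::scores(fit, display = c("sites", "species"),
                  choices = seq_len(min(2, total_rank)))))
  eig <- c(fit$CCA$eig, fit$CA$eig)
  structure(list(
    coordinates = sc$sites,
    eigenvalues = eig,
    proportion_explained = eig / fit$tot.chi,
    constrained_proportion = constrained_prop,
    species_scores = sc$species,
    biplot_scores = if (!is.null(fit$CCA)) fit$CCA$biplot else NULL,
    fit = fit), class = "rda_result")
}
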