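# Spearman co-occurrence network inference and topological-role analysis.
# Edge screening, Zi-Pi and role classification are implemented directly
# (they are the analytical core); graph storage, community detection and
# path/clustering summaries use igraph.

# --- Spearman machinery -----------------------------------------------------

.perm_cache <- new.env(parent = emptyenv())

# all permutations of 1:n as an (n! x n) index matrix
all_permutations <- function(n) {
  key <- as.character(n)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  perms <- matrix(1L, 1, 1)
  for (k in 2:n) {
    out <- matrix(0L, nrow(perms) * k, k)
    r <- 0L
    for (pos in seq_len(k)) {
      block <- cbind(perms, k)[, append(seq_len(k - 1), k, after = pos - 1),
                               drop = FALSE]
      out[r + seq_len(nrow(perms)), ] <- block
      r <- r + nrow(perms)
    }
    perms <- out
  }
  .perm_cache[[key]] <- perms
  perms
}

# null Spearman rho distribution for tie-free data: depends only on n,
# computed once per n and cached
.null_rho_cache <- new.env(parent = emptyenv())

null_rho_dist <- function(n) {
  key <- as.character(n)
  if (is.null(.null_rho_cache[[key]])) {
    P <- all_permutations(n)
    id <- seq_len(n)
    # rho between a permutation of 1..n and 1..n, via the sum of products
    s <- as.vector(P %*% id)
    mu <- n * (n + 1)^2 / 4
    v <- (n^3 - n) / 12
    .null_rho_cache[[key]] <- (s - mu) / v
  }
  .null_rho_cache[[key]]
}

# exact permutation p-value for the Spearman correlation of two vectors
# (conditional on the observed values, so ties are handled exactly)
spearman_exact_p <- function(x, y, sided = c("two", "one")) {
  sided <- match.arg(sided)
  n <- length(x)
  if (n > 9) stop("exact enumeration limited to n <= 9")
  rx <- rank(x)
  ry <- rank(y)
  obs <- stats::cor(rx, ry)
  if (!anyDuplicated(rx) && !anyDuplicated(ry)) {
    rho_null <- null_rho_dist(n)      # tie-free: depends only on n
  } else {
    P <- all_permutations(n)
    RX <- matrix(rx[P], nrow(P), n)
    # correlation against fixed ry for every permutation of rx
    rho_null <- as.vector(stats::cor(t(RX), ry))
  }
  eps <- 1e-12
  if (sided == "two") mean(abs(rho_null) >= abs(obs) - eps)
  else mean(rho_null >= obs - eps)
}

# t-approximation p-values for a matrix/vector of Spearman rho
spearman_t_p <- function(rho, n, sided = c("two", "one")) {
  sided <- match.arg(sided)
  r <- pmin(pmax(rho, -1 + 1e-15), 1 - 1e-15)
  t <- r * sqrt((n - 2) / (1 - r^2))
  p2 <- 2 * stats::pt(-abs(t), df = n - 2)
  if (sided == "two") pmin(1, p2) else pmin(1, p2 / 2)
}

#' Screen all OTU pairs for robust Spearman correlations
#'
#' Computes Spearman's rank correlation (average ranks for ties) for every
#' unordered pair of taxa and retains pairs with `|rho| >= rho_min` and
#' `p < p_max` as candidate edges. P-values are exact (full permutation
#' enumeration, valid under ties) for n <= 9 samples and use the
#' t-approximation otherwise; `p_method` can force either route.
#'
#' @param rel a `rel_abund` (correlations are computed on per-mille values).
#' @param rho_min minimum absolute correlation (default 0.6).
#' @param p_max significance cutoff, edges require `p < p_max`
#'   (default 0.01).
#' @param p_method `"auto"` (exact when n <= 9), `"exact"`, `"t_approx"`.
#' @param sided `"two"` (default) or `"one"` (observed direction).
#' @param min_occurrence taxa with fewer nonzero samples are excluded
#'   before correlation (default 3); constant taxa are skipped (rho
#'   undefined) and recorded in the `skipped` attribute.
#' @param adjust `"none"` (raw p, default) or `"BH"` (edges require
#'   `q < p_max`).
#' @return data.frame with columns `otu_a`, `otu_b`, `rho`, `p`, `sign`
#'   (`"+"`/`"-"`); attributes `params` and `skipped`.
#' @export
spearman_edge_screen <- function(rel, rho_min = 0.6, p_max = 0.01,
                                 p_method = c("auto", "exact", "t_approx"),
                                 sided = c("two", "one"),
                                 min_occurrence = 3,
                                 adjust = c("none", "BH")) {
  p_method <- match.arg(p_method)
  sided <- match.arg(sided)
  adjust <- match.arg(adjust)
  X <- rel$values
  n <- nrow(X)
  if (n < 5) stop("edge screening needs at least 5 samples")
  occ_ok <- colSums(X > 0) >= min_occurrence
  constant <- apply(X, 2, function(v) max(v) == min(v))
  skipped <- colnames(X)[!occ_ok | constant]
  X <- X[, occ_ok & !constant, drop = FALSE]
  params <- list(rho_min = rho_min, p_max = p_max, p_method = p_method,
                 sided = sided, min_occurrence = min_occurrence,
                 adjust = adjust, n_samples = n)
  empty <- data.frame(otu_a = character(), otu_b = character(),
                      rho = numeric(), p = numeric(), sign = character(),
                      stringsAsFactors = FALSE)
  if (ncol(X) < 2)
    return(structure(empty, params = params, skipped = skipped))
  R <- apply(X, 2, rank)
  rho <- stats::cor(R)
  idx <- which(upper.tri(rho) & abs(rho) >= rho_min, arr.ind = TRUE)
  if (!nrow(idx))
    return(structure(empty, params = params, skipped = skipped))
  use_exact <- p_method == "exact" || (p_method == "auto" && n <= 9)
  if (use_exact && n > 9)
    stop("exact p-values are limited to n <= 9 samples")
  rv <- rho[idx]
  p <- if (use_exact) {
    vapply(seq_len(nrow(idx)), function(k)
      spearman_exact_p(X[, idx[k, 1]], X[, idx[k, 2]], sided = sided),
      numeric(1))
  } else {
    spearman_t_p(rv, n, sided = sided)
  }
  crit <- if (adjust == "BH") bh_fdr(p) else p
  keep <- crit < p_max
  out <- data.frame(otu_a = colnames(X)[idx[keep, 1]],
                    otu_b = colnames(X)[idx[keep, 2]],
                    rho = rv[keep], p = p[keep],
                    sign = ifelse(rv[keep] >= 0, "+", "-"),
                    stringsAsFactors = FALSE)
  structure(out, params = params, skipped = skipped)
}

# --- Graph construction and topology ---------------------------------------

#' Build a signed co-occurrence network from screened edges
#'
#' Duplicate unordered pairs and self-pairs are dropped (first occurrence
#' kept); only OTUs with at least one surviving edge become nodes.
#'
#' @param edges data.frame as returned by [spearman_edge_screen()].
#' @param taxonomy optional taxonomy data.frame (rownames = OTU ids) carried
#'   onto the nodes.
#' @return object of class `cooc_network`: list with `graph` (igraph),
#'   `edges`, `params`.
#' @export
build_network <- function(edges, taxonomy = NULL) {
  params <- attr(edges, "params")
  edges <- edges[edges$otu_a != edges$otu_b, , drop = FALSE]
  key <- paste(pmin(edges$otu_a, edges$otu_b),
               pmax(edges$otu_a, edges$otu_b))
  edges <- edges[!duplicated(key), , drop = FALSE]
  if (!nrow(edges)) {
    warning("empty edge list: returning an empty network")
    g <- igraph::make_empty_graph(0, directed = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  }
  if (!is.null(taxonomy) && igraph::vcount(g) > 0) {
    ids <- igraph::V(g)$name
    for (rank in intersect(TAX_RANKS, colnames(taxonomy)))
      g <- igraph::set_vertex_attr(g, rank, value = taxonomy[ids, rank])
  }
  structure(list(graph = g, edges = edges, params = params),
            class = "cooc_network")
}

#' @export
print.cooc_network <- function(x, ...) {
  cat(sprintf("cooc_network: %d nodes, %d edges (%d +, %d -)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              sum(x$edges$sign == "+"), sum(x$edges$sign == "-")))
  invisible(x)
}

#' Detect modules by modularity maximization
#'
#' Partitions the network into modules by maximizing Newman's modularity
#' \eqn{Q = \sum_m (e_{mm} - a_m^2)}. `"louvain"` (multilevel, default) and
#' `"greedy"` (fast-greedy agglomeration) are heuristics suitable for
#' networks of hundreds to thousands of nodes; `"optimal"` solves the
#' maximization exactly (integer programming) and is only tractable for
#' small graphs. Edge signs and weights are ignored.
#'
#' @param net a `cooc_network`.
#' @param algorithm `"louvain"`, `"greedy"` or `"optimal"`.
#' @param seed RNG seed (the multilevel heuristic is stochastic).
#' @return list of class `module_partition`: `membership` (named integer),
#'   `modularity` (Q of the partition), `n_modules`, `algorithm`, `seed`.
#' @export
detect_modules <- function(net, algorithm = c("louvain", "greedy",
                                              "optimal"),
                           seed = 1) {
  algorithm <- match.arg(algorithm)
  g <- net$graph
  if (igraph::vcount(g) == 0) stop("cannot partition an empty network")
  cm <- withr::with_seed(seed, switch(algorithm,
    louvain = igraph::cluster_louvain(g, weights = NA),
    greedy = igraph::cluster_fast_greedy(g, weights = NULL),
    optimal = igraph::cluster_optimal(g, weights = NA)))
  membership <- igraph::membership(cm)
  structure(list(membership = membership,
                 modularity = igraph::modularity(g, membership),
                 n_modules = length(unique(membership)),
                 algorithm = algorithm, seed = seed),
            class = "module_partition")
}

#' Topology summary of a co-occurrence network
#'
#' Reports node/edge counts, signed edge counts, average degree
#' (avgK = 2E/N), average local clustering coefficient (avgCC; nodes of
#' degree < 2 contribute 0), average geodesic distance (avgGD; unweighted,
#' sign-blind, averaged over connected pairs only), the Newman modularity of
#' the supplied partition, module count, and the node(s) attaining the
#' maximum degree.
#'
#' @param net a `cooc_network`.
#' @param partition optional `module_partition`; when omitted, modularity
#'   and module count are `NA`.
#' @return list of class `network_topology`.
#' @export
topology_summary <- function(net, partition = NULL) {
  g <- net$graph
  n <- igraph::vcount(g)
  e <- igraph::ecount(g)
  deg <- igraph::degree(g)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  cc[is.na(cc)] <- 0
  structure(list(
    n_nodes = n, n_edges = e,
    n_positive = sum(net$edges$sign == "+"),
    n_negative = sum(net$edges$sign == "-"),
    avgK = if (n > 0) 2 * e / n else NA_real_,
    avgCC = if (n > 0) mean(cc) else NA_real_,
    avgGD = if (n > 1) igraph::mean_distance(g, directed = FALSE,
                                             unconnected = TRUE)
            else NA_real_,
    modularity = if (!is.null(partition)) partition$modularity else NA_real_,
    n_modules = if (!is.null(partition)) partition$n_modules else NA_integer_,
    max_degree = if (n > 0) max(deg) else NA_integer_,
    max_degree_nodes = if (n > 0) names(deg)[deg == max(deg)] else
      character()), class = "network_topology")
}

#' @export
print.network_topology <- function(x, ...) {
  cat(sprintf(paste0("network topology: N=%d E=%d (+%d/-%d) avgK=%.3f ",
                     "avgCC=%.3f avgGD=%.3f M=%.3f (%s modules)\n"),
              x$n_nodes, x$n_edges, x$n_positive, x$n_negative, x$avgK,
              x$avgCC, x$avgGD, x$modularity, x$n_modules))
  invisible(x)
}

# --- Zi-Pi node roles -------------------------------------------------------

#' Within-module degree (Zi) and participation coefficient (Pi)
#'
#' For node i in module s with \eqn{k_{is}} links to members of its own
#' module, \eqn{Z_i = (k_{is} - \bar{k}_s) / \sigma_s} where the mean and
#' standard deviation are taken over the within-module degrees of all
#' members of s (sample SD; a module with zero spread gives Zi = 0 for all
#' members by convention). \eqn{P_i = 1 - \sum_t (k_{it}/k_i)^2} over all
#' modules t, so a node whose links all stay inside one module has Pi = 0.
#'
#' @param net a `cooc_network`.
#' @param partition a `module_partition` covering all nodes.
#' @return data.frame with columns `node`, `module`, `degree`,
#'   `within_degree`, `Zi`, `Pi`.
#' @export
zipi <- function(net, partition) {
  g <- net$graph
  nodes <- igraph::V(g)$name
  mem <- partition$membership[nodes]
  if (any(is.na(mem))) stop("partition does not cover every network node")
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  A <- (A > 0) + 0
  mods <- sort(unique(mem))
  M <- outer(mem, mods, "==") + 0                 # node x module indicator
  K <- A %*% M                                    # k_it: links into module t
  k <- rowSums(A)
  own <- match(mem, mods)
  k_within <- K[cbind(seq_along(nodes), own)]
  z <- numeric(length(nodes))
  for (m in seq_along(mods)) {
    members <- which(own == m)
    mu <- mean(k_within[members])
    sg <- stats::sd(k_within[members])
    z[members] <- if (is.na(sg) || sg == 0) 0 else
      (k_within[members] - mu) / sg
  }
  p <- 1 - rowSums((K / k)^2)
  data.frame(node = nodes, module = mem, degree = k,
             within_degree = k_within, Zi = z, Pi = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify nodes into topological roles from (Zi, Pi)
#'
#' Four-way classification at the customary thresholds: module hubs
#' (generalists; Zi > 2.5, Pi <= 0.62), connectors (generalists; Zi <= 2.5,
#' Pi > 0.62), network hubs (supergeneralists; Zi > 2.5 and Pi > 0.62) and
#' peripherals (specialists; everything else). Values exactly at a
#' threshold fall in the lower (non-hub) category.
#'
#' @param zipi_values data.frame from [zipi()] (or any frame with `Zi`,
#'   `Pi`).
#' @param z_threshold,p_threshold role thresholds (defaults 2.5 and 0.62).
#' @return the input data.frame with an added `category` factor
#'   (`peripheral`, `connector`, `module_hub`, `network_hub`) and a
#'   `generalist` logical.
#' @export
classify_roles <- function(zipi_values, z_threshold = 2.5,
                           p_threshold = 0.62) {
  hi_z <- zipi_values$Zi > z_threshold
  hi_p <- zipi_values$Pi > p_threshold
  category <- ifelse(hi_z & hi_p, "network_hub",
              ifelse(hi_z, "module_hub",
              ifelse(hi_p, "connector", "peripheral")))
  zipi_values$category <- factor(category,
    levels = c("peripheral", "connector", "module_hub", "network_hub"))
  zipi_values$generalist <- zipi_values$category != "peripheral"
  zipi_values
}

#' Compare node roles between two networks
#'
#' @param roles_a,roles_b classified role tables (from [classify_roles()])
#'   of two networks screened with identical parameters.
#' @return list with `shared` (data.frame `node`, `category_a`,
#'   `category_b`, `shifted`), `n_generalists_a`, `n_generalists_b`,
#'   `role_shifts` (shared nodes whose category changed).
#' @export
compare_networks <- function(roles_a, roles_b) {
  shared_ids <- intersect(roles_a$node, roles_b$node)
  if (!length(shared_ids))
    warning("networks share no nodes")
  shared <- data.frame(
    node = shared_ids,
    category_a = roles_a$category[match(shared_ids, roles_a$node)],
    category_b = roles_b$category[match(shared_ids, roles_b$node)],
    stringsAsFactors = FALSE)
  shared$shifted <- as.character(shared$category_a) !=
    as.character(shared$category_b)
  list(shared = shared,
       n_generalists_a = sum(roles_a$generalist),
       n_generalists_b = sum(roles_b$generalist),
       role_shifts = shared[shared$shifted, , drop = FALSE])
}

# --- Export -----------------------------------------------------------------

#' Write network artifacts (edge list TSV, node roles TSV, GraphML)
#'
#' @param net a `cooc_network`.
#' @param roles optional classified role table.
#' @param edges_path,roles_path,graphml_path output paths (`NULL` to skip).
#' @export
write_network <- function(net, roles = NULL, edges_path = NULL,
                          roles_path = NULL, graphml_path = NULL) {
  if (!is.null(edges_path))
    utils::write.table(net$edges, edges_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(roles_path) && !is.null(roles))
    utils::write.table(roles, roles_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(graphml_path))
    igraph::write_graph(net$graph, graphml_path, format = "graphml")
  invisible(net)
}
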