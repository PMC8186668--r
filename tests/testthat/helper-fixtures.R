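# Shared fixtures and independent oracle helpers. Oracles here are written
# as plain loops/enumerations so they share no code path with the package.

# a hand-written 3-sample x 4-OTU table
tiny_table <- function() {
  counts <- matrix(c(10, 30, 60, 0,
                     5,  5,  0, 10,
                     1,  0,  0,  9),
                   nrow = 3, byrow = TRUE,
                   dimnames = list(c("s1", "s2", "s3"),
                                   c("otu1", "otu2", "otu3", "otu4")))
  taxonomy <- parse_lineage(c(
    "Bacteria;Proteobacteria;Alpha;Rhizobiales;Rhizobiaceae;Rhizobium;sp1",
    "Bacteria;Proteobacteria;Alpha;Rhizobiales;Rhizobiaceae;Agro;sp2",
    "Bacteria;Firmicutes;Bacilli;Bacillales;Bacillaceae;Bacillus;sp3",
    "Bacteria;Proteobacteria;;;;;"))
  rownames(taxonomy) <- colnames(counts)
  metadata <- data.frame(group = c("CK", "5yrCC", "10yrCC"),
                         stage = "transplanting", replicate = 1:3,
                         row.names = rownames(counts))
  otu_table(counts, taxonomy, metadata)
}

# small but fully structured synthetic configuration for fast tests
small_cfg <- function(seed = 1, ...) {
  args <- list(seed = seed, n_otus = 120, depth_range = c(5000, 9000),
               n_phyla = 8, n_classes = 14, n_orders = 24, n_families = 40,
               n_genera = 70, n_modules = 2, module_size = 8,
               n_replicates = 3)
  args[names(list(...))] <- list(...)
  do.call(synthetic_config, args)
}

# wrap a bare rel-abund matrix (samples x taxa, any scale) for functions
# that take a rel_abund
as_rel <- function(values, group = NULL) {
  md <- data.frame(group = if (is.null(group)) "g" else group,
                   stage = "s", replicate = seq_len(nrow(values)),
                   row.names = rownames(values))
  rhizonet:::new_rel_abund(values, NULL, md, steps = "test")
}

# igraph -> cooc_network via the package's own edge-list entry point
graph_to_network <- function(g, rho = 1, sign = "+") {
  if (is.null(igraph::V(g)$name))
    g <- igraph::set_vertex_attr(g, "name",
                                 value = paste0("n",
                                                seq_len(igraph::vcount(g))))
  el <- igraph::as_edgelist(g)
  d <- data.frame(otu_a = el[, 1], otu_b = el[, 2],
                  rho = rho, p = 0, sign = sign,
                  stringsAsFactors = FALSE)
  build_network(d)
}

# all set partitions of n elements (for the exhaustive modularity oracle)
all_set_partitions <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_set_partitions(n - 1)) {
    k <- max(p)
    for (m in seq_len(k + 1)) out[[length(out) + 1]] <- c(p, m)
  }
  out
}

# independent Zi/Pi hand-count: explicit per-node neighbour loops
zipi_oracle <- function(g, membership) {
  nodes <- igraph::V(g)$name
  adj <- igraph::as_adj_list(g)
  k_in <- numeric(length(nodes))
  deg <- numeric(length(nodes))
  k_to <- matrix(0, length(nodes), length(unique(membership)),
                 dimnames = list(nodes, sort(unique(membership))))
  for (i in seq_along(nodes)) {
    nb <- names(adj[[i]])
    deg[i] <- length(nb)
    for (b in nb) {
      k_to[i, as.character(membership[b])] <-
        k_to[i, as.character(membership[b])] + 1
      if (membership[b] == membership[nodes[i]])
        k_in[i] <- k_in[i] + 1
    }
  }
  z <- numeric(length(nodes))
  for (i in seq_along(nodes)) {
    same <- which(membership[nodes] == membership[nodes[i]])
    s <- stats::sd(k_in[same])
    z[i] <- if (is.na(s) || s == 0) 0 else (k_in[i] - mean(k_in[same])) / s
  }
  p <- 1 - rowSums((k_to / deg)^2)
  data.frame(node = nodes, Zi = z, Pi = unname(p),
             stringsAsFactors = FALSE)
}

# independent exhaustive two-sided Spearman permutation p (loop-based)
spearman_p_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  obs <- abs(stats::cor(rx, ry))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  vals <- vapply(perms(rx), function(pr) stats::cor(pr, ry), numeric(1))
  mean(abs(vals) >= obs - 1e-12)
}

# random graph with no isolated vertices and named nodes
random_named_graph <- function(n, p) {
  g <- igraph::sample_gnp(n, p)
  g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0))
  igraph::set_vertex_attr(g, "name",
                          value = paste0("n", seq_len(igraph::vcount(g))))
}
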