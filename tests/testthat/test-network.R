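test_that("Spearman screen retains strong pairs and uses exact enumeration
           at small n", {
  # n = 15 concordant pair: retained with sign +; anti-concordant: sign -
  x <- 1:15
  v <- cbind(a = x, b = x + 0.5, c = rev(x) * 2,
             d = withr::with_seed(3, rnorm(15, 50, 1)))
  rownames(v) <- paste0("s", 1:15)
  edges <- spearman_edge_screen(as_rel(v), min_occurrence = 1)
  key <- paste(edges$otu_a, edges$otu_b)
  expect_true("a b" %in% key)
  expect_equal(edges$rho[key == "a b"], 1)
  expect_equal(edges$sign[key == "a c"], "-")
  expect_equal(edges$rho[key == "a c"], -1)

  # n = 5 perfect concordance: exact two-sided p = 2/120 > 0.01 -> no edge
  v5 <- cbind(a = 1:5, b = c(2, 4, 6, 9, 11), c = c(5, 1, 4, 2, 3))
  rownames(v5) <- paste0("s", 1:5)
  e5 <- spearman_edge_screen(as_rel(v5), min_occurrence = 1)
  expect_equal(nrow(e5), 0)
  expect_equal(rhizonet:::spearman_exact_p(v5[, "a"], v5[, "b"]), 2 / 120)

  # constant and sparse taxa are excluded up front
  v2 <- cbind(v, const = 7, rare = c(1, rep(0, 14)))
  e2 <- spearman_edge_screen(as_rel(v2), min_occurrence = 3)
  expect_setequal(attr(e2, "skipped"), c("const", "rare"))
  expect_error(spearman_edge_screen(as_rel(v5[1:4, ])), "5 samples")
})

test_that("exact permutation p-values match an independent enumeration
           oracle, with and without ties", {
  for (s in 1:6) {
    n <- 5 + (s %% 2)
    x <- withr::with_seed(s, sample(1:4, n, replace = TRUE))  # ties likely
    y <- withr::with_seed(s + 50, rnorm(n))
    expect_equal(rhizonet:::spearman_exact_p(x, y),
                 spearman_p_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("network construction deduplicates edges and drops isolates", {
  d <- data.frame(otu_a = c("a", "b", "c", "b", "a"),
                  otu_b = c("b", "c", "a", "a", "a"),
                  rho = c(0.9, 0.8, 0.7, 0.9, 1), p = 0.001,
                  sign = c("+", "+", "-", "+", "+"))
  net <- build_network(d)                 # self loop a-a dropped, b-a dup
  expect_equal(igraph::vcount(net$graph), 3)
  expect_equal(igraph::ecount(net$graph), 3)
  expect_warning(empty <- build_network(d[0, ]), "empty")
  expect_equal(igraph::vcount(empty$graph), 0)
})

test_that("topology summary matches hand counts on canonical graphs", {
  tri <- graph_to_network(igraph::make_graph(~ a - b, b - c, c - a))
  t1 <- topology_summary(tri)
  expect_equal(t1$avgCC, 1)
  expect_equal(t1$avgGD, 1)
  expect_equal(t1$avgK, 2)

  path <- graph_to_network(igraph::make_graph(~ a - b, b - c))
  t2 <- topology_summary(path)
  expect_equal(t2$avgCC, 0)
  expect_equal(t2$avgGD, (1 + 1 + 2) / 3)
  expect_equal(t2$max_degree_nodes, "b")

  # avgK = 2E/N and sign accounting hold on random screened graphs
  for (s in 1:5) {
    g <- withr::with_seed(s, random_named_graph(25, 0.15))
    signs <- withr::with_seed(s, sample(c("+", "-"), igraph::ecount(g),
                                        replace = TRUE))
    net <- graph_to_network(g, sign = signs)
    topo <- topology_summary(net)
    expect_equal(topo$avgK, 2 * topo$n_edges / topo$n_nodes)
    expect_equal(topo$n_positive + topo$n_negative, topo$n_edges)
  }
})

test_that("module detection maximizes Q on canonical graphs and assigns
           every node once", {
  twotri <- graph_to_network(igraph::make_graph(~ a - b, b - c, c - a,
                                                d - e, e - f, f - d))
  for (alg in c("louvain", "greedy", "optimal")) {
    part <- detect_modules(twotri, algorithm = alg, seed = 1)
    expect_equal(part$modularity, 0.5)
    expect_equal(part$n_modules, 2)
    expect_equal(sort(names(part$membership)), sort(letters[1:6]))
  }
  k5 <- graph_to_network(igraph::make_full_graph(5))
  pk <- detect_modules(k5, algorithm = "optimal", seed = 1)
  expect_equal(pk$n_modules, 1)
  expect_equal(pk$modularity, 0)
  expect_error(detect_modules(k5, algorithm = "metis"), "arg")
})

test_that("Zi-Pi follows the worked formulas and degenerate conventions", {
  # two 4-cliques joined by a bridge node x with 2 links into each clique
  g <- igraph::make_graph(~ a - b, a - c, a - d, b - c, b - d, c - d,
                          e - f, e - h, e - i, f - h, f - i, h - i,
                          x - a, x - b, x - e, x - f)
  net <- graph_to_network(g)
  mem <- c(a = 1, b = 1, c = 1, d = 1, e = 2, f = 2, h = 2, i = 2, x = 1)
  part <- structure(list(membership = mem,
                         modularity = igraph::modularity(
                           net$graph, mem[igraph::V(net$graph)$name]),
                         n_modules = 2, algorithm = "manual", seed = 1),
                    class = "module_partition")
  zp <- zipi(net, part)
  rownames(zp) <- zp$node
  # node x: degree 4, 2 links in its own module, 2 in the other
  expect_equal(zp["x", "Pi"], 1 - (0.5^2 + 0.5^2))
  # c and d have all links within their module
  expect_equal(zp["c", "Pi"], 0)
  expect_equal(zp["d", "Pi"], 0)
  # clique 2 members all have equal within-degree -> sd 0 -> Zi = 0
  expect_equal(zp[c("e", "f", "h", "i"), "Zi"], rep(0, 4),
               ignore_attr = TRUE)
  # k_it sums back to the degree for every node
  expect_equal(zp$within_degree <= zp$degree, rep(TRUE, 9))

  # matches the independent hand-count oracle on random partitions
  for (s in 1:10) {
    g2 <- withr::with_seed(s, random_named_graph(10, 0.35))
    net2 <- graph_to_network(g2)
    nodes <- igraph::V(net2$graph)$name
    mem2 <- withr::with_seed(s + 10,
      stats::setNames(sample(1:3, length(nodes), replace = TRUE), nodes))
    part2 <- structure(list(membership = mem2), class = "module_partition")
    zp2 <- zipi(net2, part2)
    orc <- zipi_oracle(net2$graph, mem2)
    expect_equal(zp2$Zi, orc$Zi[match(zp2$node, orc$node)],
                 tolerance = 1e-12)
    expect_equal(zp2$Pi, orc$Pi[match(zp2$node, orc$node)],
                 tolerance = 1e-12)
  }
})

test_that("role classification applies the Zi-Pi threshold rules with
           equality in the lower category", {
  grid <- data.frame(
    Zi = c(3.0, 1.0, 0.0, 3.0, 2.5, 2.5, 3.0, -1),
    Pi = c(0.5, 0.7, 0.0, 0.7, 0.62, 0.70, 0.62, 0.62))
  roles <- classify_roles(grid)
  expect_equal(as.character(roles$category),
               c("module_hub", "connector", "peripheral", "network_hub",
                 "peripheral", "connector", "module_hub", "peripheral"))
  expect_equal(roles$generalist,
               c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE, FALSE))
})

test_that("network comparison tracks shared nodes, shifts and generalist
           totals", {
  mk_roles <- function(nodes, zi, pi) {
    classify_roles(data.frame(node = nodes, Zi = zi, Pi = pi))
  }
  a <- mk_roles(c("x", "y", "z"), c(3, 0, 0), c(0.5, 0.7, 0))
  b <- mk_roles(c("x", "y", "w"), c(0, 0, 3), c(0.5, 0.7, 0.7))
  cmp <- compare_networks(a, b)
  expect_setequal(cmp$shared$node, c("x", "y"))
  expect_equal(cmp$role_shifts$node, "x")       # module_hub -> peripheral
  expect_equal(cmp$n_generalists_a, 2)          # x and y
  expect_equal(cmp$n_generalists_b, 2)          # y and w (w not shared)
  expect_equal(cmp$n_generalists_a,
               sum(a$category %in% c("connector", "module_hub",
                                     "network_hub")))
  same <- compare_networks(a, a)
  expect_equal(nrow(same$role_shifts), 0)
  expect_warning(compare_networks(a, mk_roles("q", 0, 0)), "share no")
})
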