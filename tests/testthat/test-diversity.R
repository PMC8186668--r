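test_that("alpha diversity matches closed forms", {
  expect_equal(alpha_diversity(c(5, 5, 5, 5), "shannon"), 2)
  expect_equal(alpha_diversity(c(10, 0, 0), "observed_otus"), 1)
  expect_equal(alpha_diversity(c(10, 0, 0), "shannon"), 0)
  x <- c(3, 9, 1, 7)
  expect_equal(alpha_diversity(x, "shannon"),
               alpha_diversity(10 * x, "shannon"))
  expect_error(alpha_diversity(c(0, 0), "shannon"), "empty sample")
})

test_that("Faith PD spans observed tips to the root and is monotone", {
  star <- ape::read.tree(text = "(a:1,b:1,c:1,d:1);")
  x <- c(a = 1, b = 2, c = 0, d = 0)
  expect_equal(faith_pd(x, star), 2)
  expect_equal(faith_pd(c(a = 1, b = 1, c = 1, d = 1), star), 4)
  # nested observation sets give non-decreasing PD
  tree <- withr::with_seed(5, ape::rcoal(8))
  x <- stats::setNames(numeric(8), tree$tip.label)
  pds <- vapply(1:8, function(k) {
    x[k] <<- 1
    faith_pd(x, tree)
  }, numeric(1))
  expect_true(all(diff(pds) >= -1e-12))
  expect_equal(pds[8], sum(tree$edge.length))
  expect_error(faith_pd(c(zz = 1), tree), "zz")
})

test_that("Faith PD agrees with picante on binary trees", {
  tree <- withr::with_seed(11, ape::rcoal(10))
  m <- withr::with_seed(12,
    matrix(rbinom(30, 1, 0.6) * rpois(30, 5), 3,
           dimnames = list(paste0("s", 1:3), tree$tip.label)))
  m[1, ] <- pmax(m[1, ], 1)  # avoid an empty row
  ours <- faith_pd(m, tree)
  ref <- picante::pd(m, tree, include.root = TRUE)$PD
  expect_equal(unname(ours), ref, tolerance = 1e-9)
})

test_that("rarefaction matches the hypergeometric expectation and is exact
           at full depth", {
  counts <- matrix(c(1, 1, 1, 1,
                     2, 2, 0, 0), 2, byrow = TRUE,
                   dimnames = list(c("s1", "s2"), paste0("o", 1:4)))
  tax <- parse_lineage(rep("B;P;C;O;F;G;S", 4))
  rownames(tax) <- colnames(counts)
  md <- data.frame(group = "CK", stage = "t", replicate = 1:2,
                   row.names = rownames(counts))
  tab <- otu_table(counts, tax, md)

  rc <- rarefaction_curve(tab, depths = c(1, 2, 4), n_draws = 30, seed = 3)
  # oracle for s1 ([1,1,1,1], depth 2): all C(4,2) subsamples have 2 OTUs
  expect_equal(rc$expected["s1", "2"], 2)
  expect_equal(rc$mean["s1", "2"], 2)         # every draw is exactly 2
  # one read always hits exactly one OTU
  expect_equal(rc$expected["s2", "1"], 1)
  expect_equal(rc$mean["s2", "1"], 1)
  # full-depth draw is exhaustive: mean = unrarefied richness, sd = 0
  expect_equal(rc$mean["s1", "4"], 4)
  expect_equal(rc$sd["s1", "4"], 0)
  expect_equal(rc$mean["s2", "4"], 2)
  w <- testthat::capture_warnings(rarefaction_curve(tab, depths = 10,
                                                    n_draws = 2))
  expect_match(w, "exceeds", all = FALSE)
})

test_that("random subsampling converges to the closed-form richness", {
  row <- withr::with_seed(8, rpois(12, 8) + 1)
  counts <- matrix(row, 1, dimnames = list("s", paste0("o", 1:12)))
  tax <- parse_lineage(rep("B;P;C;O;F;G;S", 12))
  rownames(tax) <- colnames(counts)
  tab <- otu_table(counts, tax,
                   data.frame(group = "g", stage = "t", replicate = 1,
                              row.names = "s"))
  d <- floor(sum(row) / 2)
  rc <- rarefaction_curve(tab, depths = d, n_draws = 100, seed = 4)
  se <- rc$sd["s", 1] / sqrt(100)
  expect_lt(abs(rc$mean["s", 1] - rc$expected["s", 1]), 3 * se + 1e-9)
})

test_that("Bray-Curtis follows the L1 formula", {
  v <- rbind(s1 = c(600, 400), s2 = c(400, 600), s3 = c(600, 400),
             s4 = c(1000, 0))
  dm <- as.matrix(bray_curtis(as_rel(v)))
  expect_equal(dm["s1", "s3"], 0)
  expect_equal(dm["s1", "s2"], 0.2)
  d5 <- as.matrix(bray_curtis(as_rel(rbind(a = c(1000, 0),
                                           b = c(0, 1000)))))
  expect_equal(d5["a", "b"], 1)
})

test_that("weighted UniFrac equals branch-enumeration values", {
  # hand-enumerated tree: ((a:1,b:2):1,c:3);
  tree <- ape::read.tree(text = "((a:1,b:2):1,c:3);")
  v <- rbind(A = c(a = 500, b = 0, c = 500),
             B = c(a = 0, b = 1000, c = 0),
             C = c(a = 500, b = 0, c = 500))
  rel <- as_rel(v)
  raw <- as.matrix(weighted_unifrac(rel, tree, normalized = FALSE))
  # branches: a(1)*|.5-0| + b(2)*|0-1| + ab(1)*|.5-1| + c(3)*|.5-0| = 4.5
  expect_equal(raw["A", "B"], 4.5)
  expect_equal(raw["A", "C"], 0)
  nrm <- as.matrix(weighted_unifrac(rel, tree, normalized = TRUE))
  # normalizer: 1*.5 + 2*1 + 1*1.5 + 3*.5 = 5.5
  expect_equal(nrm["A", "B"], 4.5 / 5.5)

  # star tree with unit branches: each tip contributes |p_i - q_i| once,
  # so raw wUF equals the full L1 distance between proportion vectors;
  # disjoint single-taxon samples have normalized distance 1
  star <- ape::read.tree(text = "(a:1,b:1,c:1,d:1);")
  p <- withr::with_seed(2, {
    m <- matrix(rexp(12), 3, dimnames = list(paste0("s", 1:3),
                                             c("a", "b", "c", "d")))
    m / rowSums(m) * 1000
  })
  raw_star <- as.matrix(weighted_unifrac(as_rel(p), star,
                                         normalized = FALSE))
  l1 <- as.matrix(stats::dist(p / 1000, method = "manhattan"))
  expect_equal(raw_star, l1, tolerance = 1e-12)
  disj <- rbind(A = c(a = 1000, b = 0, c = 0, d = 0),
                B = c(a = 0, b = 1000, c = 0, d = 0))
  expect_equal(as.matrix(weighted_unifrac(as_rel(disj), star))["A", "B"],
               1)
})

test_that("PCoA reproduces collinear geometry and reports negative
           eigenvalues", {
  x <- c(0, 3, 5)
  dm <- stats::dist(x)
  ord <- pcoa(dm)
  ax1 <- ord$coordinates[, 1]
  expect_equal(as.matrix(stats::dist(ax1)), as.matrix(dm),
               ignore_attr = TRUE, tolerance = 1e-9)
  expect_equal(ord$proportion_explained[1], 1)

  zero <- matrix(0, 3, 3)
  expect_equal(unname(pcoa(stats::as.dist(zero))$eigenvalues),
               rep(0, 3), tolerance = 1e-12)
  m <- matrix(c(0, 1, 2, 0), 2)
  expect_error(pcoa(m), "symmetric")

  # Euclidean input: no meaningful negative eigenvalues
  pts <- withr::with_seed(3, matrix(rnorm(20), 5))
  e <- pcoa(stats::dist(pts))$eigenvalues
  expect_true(all(e > -1e-8 * max(e)))
})

test_that("PERMANOVA separates duplicated groups at the permutation floor
           and is seed-reproducible", {
  pts <- rbind(matrix(0, 4, 2), matrix(10, 4, 2)) +
    withr::with_seed(9, matrix(rnorm(16, sd = 1e-3), 8))
  dm <- stats::dist(pts)
  labels <- rep(c("A", "B"), each = 4)
  res <- permanova(dm, labels, n_permutations = 99, seed = 7)
  expect_equal(res$p_value, 1 / 100)
  expect_gt(res$R2, 0.99)
  expect_true(res$R2 >= 0 && res$R2 <= 1)
  res2 <- permanova(dm, labels, n_permutations = 99, seed = 7)
  expect_identical(res$p_value, res2$p_value)
  expect_error(permanova(dm, c("A", rep("B", 7)), 99), "size 1")
})

test_that("RDA recovers a perfectly linear constraint and reduces to PCA
           without constraints", {
  n <- 12
  x <- seq_len(n)
  Y <- outer(x, c(2, -1, 0.5)) + 5
  rownames(Y) <- paste0("s", 1:n)
  rel <- as_rel(Y)
  res <- rda_constrained(rel, data.frame(x = x, row.names = rownames(Y)),
                         transform = "none")
  expect_equal(res$constrained_proportion, 1, tolerance = 1e-9)

  # orthogonal constraint explains almost nothing
  Y2 <- withr::with_seed(21, matrix(rexp(12 * 6), 12,
                                    dimnames = list(paste0("s", 1:12),
                                                    paste0("t", 1:6))))
  z <- withr::with_seed(22, rnorm(12))
  res2 <- rda_constrained(as_rel(Y2),
                          data.frame(z = z, row.names = rownames(Y2)),
                          transform = "none")
  expect_lt(res2$constrained_proportion, 0.25)

  # no constraints: eigenvalues match a direct PCA of the response
  res3 <- rda_constrained(as_rel(Y2), NULL, transform = "none")
  pc <- stats::prcomp(Y2, center = TRUE, scale. = FALSE)
  expect_equal(unname(res3$eigenvalues) / sum(res3$eigenvalues),
               pc$sdev^2 / sum(pc$sdev^2), tolerance = 1e-9)

  # collinear constraints are reported
  cst <- data.frame(a = x, b = 2 * x, row.names = rownames(Y))
  expect_error(rda_constrained(rel, cst, transform = "none"), "collinear")
})
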