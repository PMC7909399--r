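test_that("Mantel statistic behaves under identity, monotone maps and matches vegan", {
  set.seed(2)
  d1 <- dist(matrix(rnorm(15 * 3), 15))
  dm1 <- dist_matrix(d1, "dissimilarity", ids = paste0("s", 1:15))
  mt <- mantel_test(dm1, dm1, n_perm = 99, seed = 1)
  expect_equal(mt$statistic, 1, tolerance = 1e-12)
  # rank invariance under a monotone transform
  dm_sq <- dist_matrix(as.matrix(d1)^2, "dissimilarity")
  expect_equal(mantel_test(dm1, dm_sq, n_perm = 99)$statistic, 1,
               tolerance = 1e-12)
  # statistic equals vegan's (both methods)
  d2 <- dist(matrix(rnorm(15 * 3), 15))
  dm2 <- dist_matrix(d2, "dissimilarity", ids = paste0("s", 1:15))
  for (meth in c("spearman", "pearson")) {
    expect_equal(mantel_test(dm1, dm2, method = meth, n_perm = 99)$statistic,
                 unname(vegan::mantel(d1, d2, method = meth,
                                      permutations = 0)$statistic),
                 tolerance = 1e-12)
  }
  expect_error(mantel_test(dm1, dist_matrix(dist(rnorm(4)), "dissimilarity")),
               "size")
})

test_that("ANOSIM attains 1 at complete separation and matches vegan", {
  sep <- separated_dist()
  an <- anosim_test(sep$d, sep$groups, n_perm = 99, seed = 1)
  expect_equal(an$statistic, 1)
  expect_lte(an$p, 0.05)
  # vegan agreement on unstructured data
  set.seed(6)
  d <- dist(matrix(rnorm(18 * 4), 18))
  g <- rep(1:3, each = 6)
  mine <- anosim_test(dist_matrix(d, "dissimilarity",
                                  ids = paste0("s", 1:18)), g, n_perm = 99)
  expect_equal(mine$statistic,
               unname(vegan::anosim(d, g, permutations = 0)$statistic),
               tolerance = 1e-12)
  # relabeling (swapping group names) leaves R unchanged
  swapped <- anosim_test(dist_matrix(d, "dissimilarity",
                                     ids = paste0("s", 1:18)),
                         c("B", "A", "C")[g], n_perm = 99)
  expect_equal(swapped$statistic, mine$statistic)
  expect_error(anosim_test(sep$d, c(1, rep(2, 7))), "at least two samples")
})

test_that("mean ANOSIM R over random relabelings is near zero", {
  set.seed(10)
  d <- dist_matrix(dist(matrix(rnorm(16 * 3), 16)), "dissimilarity",
                   ids = paste0("s", 1:16))
  rs <- vapply(1:1000, function(i) {
    g <- sample(rep(1:2, each = 8))
    anosim_test(d, g, n_perm = 99, seed = i)$statistic
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.02)
})

test_that("PERMANOVA equals classical ANOVA on univariate Euclidean data", {
  set.seed(14)
  for (i in 1:5) {
    x <- rnorm(21) + rep(c(0, 0.5, 1), each = 7)
    g <- rep(c("a", "b", "c"), each = 7)
    d <- dist_matrix(dist(x), "dissimilarity", ids = paste0("s", 1:21))
    pf <- permanova_test(d, g, n_perm = 0)$statistic
    af <- summary(stats::aov(x ~ factor(g)))[[1]]$`F value`[1]
    expect_equal(pf, af, tolerance = 1e-10)
  }
  # agreement with vegan::adonis2 as a second route
  x <- rnorm(20)
  g <- rep(1:2, each = 10)
  d <- dist_matrix(dist(x), "dissimilarity", ids = paste0("s", 1:20))
  expect_equal(permanova_test(d, g, n_perm = 0)$statistic,
               vegan::adonis2(dist(x) ~ factor(g), permutations = 2)$F[1],
               tolerance = 1e-10)
  # degenerate distances are refused
  zero <- dist_matrix(matrix(0, 6, 6), "dissimilarity")
  expect_error(permanova_test(zero, rep(1:2, each = 3)), "degenerate")
})

test_that("ANOSIM and PERMANOVA are invariant to sample reordering", {
  set.seed(17)
  d <- dist(matrix(rnorm(14 * 3), 14))
  g <- rep(1:2, each = 7)
  dm <- dist_matrix(d, "dissimilarity", ids = paste0("s", 1:14))
  pm <- sample(14)
  m <- as.matrix(dm)
  dm_p <- dist_matrix(m[pm, pm], "dissimilarity")
  expect_equal(anosim_test(dm, g, n_perm = 99)$statistic,
               anosim_test(dm_p, g[pm], n_perm = 99)$statistic,
               tolerance = 1e-12)
  expect_equal(permanova_test(dm, g, n_perm = 0)$statistic,
               permanova_test(dm_p, g[pm], n_perm = 0)$statistic,
               tolerance = 1e-12)
})

test_that("Kruskal-Wallis letters separate what the data separate", {
  kl <- kruskal_letters(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(kl$H, 3.857, tolerance = 1e-3)
  # all-equal data: no separation, shared letter
  kl0 <- kruskal_letters(rep(2, 8), rep(c("a", "b"), each = 4))
  expect_equal(kl0$H, 0)
  expect_equal(unname(kl0$letters), c("a", "a"))
  # three fully separated groups get three distinct letters
  v <- c(1:5, 11:15, 21:25)
  g <- rep(c("lo", "mid", "hi"), each = 5)
  kl3 <- kruskal_letters(v, g)
  expect_lt(kl3$p, 0.05)
  expect_equal(length(unique(kl3$letters)), 3)
  # overlapping groups share letters
  set.seed(3)
  v2 <- c(rnorm(6), rnorm(6, 0.1), rnorm(6, 5))
  g2 <- rep(c("a", "b", "c"), each = 6)
  kl2 <- kruskal_letters(v2, g2)
  expect_equal(kl2$letters[["a"]], kl2$letters[["b"]])
  expect_false(kl2$letters[["c"]] == kl2$letters[["a"]])
})

test_that("the permutation difference-of-means test matches enumeration", {
  wt <- whites_test(c(0.9, 0.8, 0.85), c(0.1, 0.2, 0.15))
  expect_true(wt$exact)
  expect_equal(wt$p, 2 * choose(3, 3) / choose(6, 3))   # = 0.1
  # identical groups
  w0 <- whites_test(c(0.3, 0.4), c(0.3, 0.4))
  expect_equal(w0$statistic, 0)
  expect_equal(w0$p, 1)
  # zero pooled variance convention
  wz <- whites_test(c(0.2, 0.2, 0.2), c(0.2, 0.2))
  expect_equal(wz$p, 1)
  # antisymmetry in the group order
  wa <- whites_test(c(0.9, 0.8, 0.85), c(0.1, 0.2, 0.15))
  wb <- whites_test(c(0.1, 0.2, 0.15), c(0.9, 0.8, 0.85))
  expect_equal(wa$statistic, -wb$statistic)
  expect_equal(wa$p, wb$p)
  # sampled path is deterministic given the seed
  set.seed(1)
  x <- runif(10); y <- runif(10, 0.2)
  s1 <- whites_test(x, y, n_perm = 499, max_exact = 10, seed = 7)
  s2 <- whites_test(x, y, n_perm = 499, max_exact = 10, seed = 7)
  expect_false(s1$exact)
  expect_identical(s1, s2)
})

test_that("BH adjustment is the step-up procedure with guardrails", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  set.seed(4)
  p <- runif(25)
  q <- bh_adjust(p)
  expect_true(all(q >= p - 1e-15))
  expect_true(all(q <= 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  expect_error(bh_adjust(c(0.5, NA)), "0, 1")
})
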