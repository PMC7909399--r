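test_that("alpha-diversity indices match their closed forms", {
  cm <- community_matrix(rbind(S1 = c(2, 2, 2, 2),
                               S2 = c(5, 1, 1, 2, 2, 3)[1:4]))
  a <- alpha_diversity(cm)
  expect_equal(a$shannon[1], log(4), tolerance = 1e-12)
  expect_equal(a$invsimpson[1], 4, tolerance = 1e-12)
  expect_equal(a$chao1[1], 4)

  cm2 <- community_matrix(rbind(S1 = c(5, 1, 1, 2, 2, 3)))
  a2 <- alpha_diversity(cm2)
  expect_equal(a2$S_obs, 6)
  expect_equal(a2$F1, 2)
  expect_equal(a2$F2, 2)
  expect_equal(a2$chao1, 6 + 2 * 1 / (2 * 3), tolerance = 1e-12)

  cm3 <- community_matrix(rbind(S1 = c(100)))
  a3 <- alpha_diversity(cm3)
  expect_equal(a3$shannon, 0)
  expect_equal(a3$invsimpson, 1)

  expect_error(alpha_diversity(community_matrix(rbind(S1 = c(0, 0), S2 = c(1, 1)))),
               "empty sample")
})

test_that("Chao1 equals observed richness when singletons are absent and Shannon is maximal at uniformity", {
  set.seed(8)
  for (i in 1:20) {
    v <- sample(2:9, 12, replace = TRUE)   # no singletons by construction
    a <- alpha_diversity(community_matrix(rbind(S = v)))
    expect_equal(a$chao1, a$S_obs)
    expect_lte(a$shannon, log(a$S_obs) + 1e-12)
  }
  u <- alpha_diversity(community_matrix(rbind(S = rep(7, 9))))
  expect_equal(u$shannon, log(9), tolerance = 1e-12)
})

test_that("rarefaction curves are deterministic, anchored and monotone", {
  cm <- community_matrix(rbind(S = rep(10L, 50)))
  # depth = total reproduces the observed-sample statistic exactly
  full <- rarefaction_curve(cm, depths = 500, reps = 1, seed = 1)
  expect_equal(full$value, alpha_diversity(cm)$chao1)
  r1 <- rarefaction_curve(cm, depths = c(10, 50, 500), reps = 20, seed = 5,
                          statistic = "richness")
  r2 <- rarefaction_curve(cm, depths = c(10, 50, 500), reps = 20, seed = 5,
                          statistic = "richness")
  expect_identical(r1, r2)
  expect_true(all(diff(r1$value) >= 0))
  expect_warning(rarefaction_curve(cm, depths = 501, reps = 1, seed = 1),
                 "truncated")
})

test_that("Bray-Curtis matches hand-computed values and its invariants", {
  cm <- community_matrix(rbind(A = c(6, 2), B = c(2, 2), C = c(6, 2)))
  d <- as.matrix(bray_curtis(cm))
  expect_equal(d["A", "B"], 4 / 12, tolerance = 1e-12)
  expect_equal(d["A", "C"], 0)
  disj <- bray_curtis(community_matrix(rbind(A = c(1, 0), B = c(0, 1))))
  expect_equal(as.matrix(disj)["A", "B"], 1)
  sim <- small_sim(nu = 0.5, seed = 2, n_species = 80, reads = 400)
  m <- as.matrix(bray_curtis(sim$cm))
  expect_true(all(m >= 0 & m <= 1))
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(0, nrow(m)))
  expect_error(bray_curtis(community_matrix(rbind(A = c(0, 0), B = c(1, 1)))),
               "zero total")
})

test_that("group overlap counts shared and exclusive OTUs by enumeration", {
  # 4 groups x 2 samples; 3 OTUs everywhere, 2 exclusive per group
  groups <- rep(paste0("G", 1:4), each = 2)
  shared <- matrix(1L, 8, 3)
  excl <- matrix(0L, 8, 8)
  for (g in 1:4) excl[(2 * g - 1):(2 * g), (2 * g - 1):(2 * g)] <- 1L
  cm <- community_matrix(cbind(shared, excl))
  ov <- group_overlap(cm, groups)
  expect_equal(ov$shared_all, 3)
  expect_equal(unname(ov$exclusive), rep(2L, 4))
  expect_equal(unname(ov$per_group), rep(5L, 4))
  expect_equal(ov$total_otus, 11)
  # sum(exclusive) + shared-by->=2 = total
  expect_equal(sum(ov$exclusive) + 3, ov$total_otus)
  # single group: everything shared and exclusive to it
  ov1 <- group_overlap(toy_cm(), rep("only", 3))
  expect_equal(ov1$shared_all, 5)
  expect_equal(unname(ov1$exclusive), 5L)
  expect_error(group_overlap(toy_cm(), c("a", "b")), "match")
})

test_that("within-group beta uses only within-group pairs", {
  m <- matrix(0.9, 5, 5)
  m[1:3, 1:3] <- rbind(c(0, 0.2, 0.4), c(0.2, 0, 0.6), c(0.4, 0.6, 0))
  m[4, 5] <- m[5, 4] <- 0.3
  diag(m) <- 0
  d <- dist_matrix(m, "dissimilarity")
  g <- c("A", "A", "A", "B", "B")
  wb <- within_group_beta(d, g)
  expect_equal(wb$mean[wb$group == "A"], 0.4, tolerance = 1e-12)
  expect_equal(wb$sd[wb$group == "A"], 0.2, tolerance = 1e-12)
  # population SD convention
  wbp <- within_group_beta(d, g, sd_type = "population")
  expect_equal(wbp$sd[wbp$group == "A"], sqrt(2 / 3) * 0.2,
               tolerance = 1e-12)
  # invariance to between-group entries
  m2 <- m
  m2[1:3, 4:5] <- 0.123
  m2[4:5, 1:3] <- 0.123
  wb2 <- within_group_beta(dist_matrix(m2, "dissimilarity"), g)
  expect_equal(wb$mean, wb2$mean)
  # singleton group reported missing
  wb3 <- within_group_beta(d, c("A", "A", "A", "B", "C"))
  expect_true(is.na(wb3$mean[wb3$group == "C"]))
})

test_that("UPGMA trees have the forced geometry and recover ultrametric input", {
  two <- dist_matrix(matrix(c(0, 0.4, 0.4, 0), 2,
                            dimnames = list(c("A", "B"), c("A", "B"))),
                     "dissimilarity")
  nwk <- upgma_tree(two)
  phy <- attr(nwk, "phylo")
  expect_setequal(phy$tip.label, c("A", "B"))
  expect_equal(unname(phy$edge.length), c(0.2, 0.2))

  m3 <- matrix(c(0, 0.2, 0.6, 0.2, 0, 0.6, 0.6, 0.6, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  phy3 <- attr(upgma_tree(dist_matrix(m3, "dissimilarity")), "phylo")
  # ((A,B),C): A and B are siblings
  coph <- ape::cophenetic.phylo(phy3)
  expect_lt(coph["A", "B"], coph["A", "C"])
  expect_equal(coph["A", "C"], coph["B", "C"])

  # ultrametric distances are reproduced exactly
  set.seed(4)
  base <- hclust(dist(matrix(rnorm(8 * 3), 8)), method = "average")
  ultra <- as.matrix(cophenetic(base))
  phy_u <- attr(upgma_tree(dist_matrix(ultra, "dissimilarity")), "phylo")
  coph_u <- ape::cophenetic.phylo(phy_u)[rownames(ultra), colnames(ultra)]
  expect_equal(coph_u, ultra, tolerance = 1e-10)
})
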