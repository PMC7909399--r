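test_that("Hellinger transform matches the formula and is compositional", {
  h <- hellinger(matrix(c(1, 1, 2), 1))
  expect_equal(as.vector(h), c(0.5, 0.5, sqrt(0.5)), tolerance = 1e-6)
  expect_equal(sum(h^2), 1, tolerance = 1e-12)
  one_col <- hellinger(matrix(c(3, 7, 2), 3))
  expect_equal(as.vector(one_col), rep(1, 3))
  m <- matrix(c(1, 2, 3, 4, 5, 6), 2, byrow = TRUE)
  expect_equal(hellinger(m), hellinger(m * 10), tolerance = 1e-12)
  expect_error(hellinger(rbind(c(0, 0), c(1, 2))), "zero row")
})

test_that("RDA fit agrees with per-column least squares and is basis-invariant", {
  set.seed(21)
  Y <- matrix(rnorm(30 * 5), 30)
  X <- matrix(rnorm(30 * 3), 30)
  fit <- rda_fit(Y, X, n_perm = 0)
  # oracle: column-by-column OLS on the standardized predictors
  Xs <- scale(X)
  oracle <- apply(scale(Y, scale = FALSE), 2, function(y)
    stats::lm.fit(cbind(1, Xs), y)$fitted.values)
  expect_equal(unname(fit$fitted), unname(oracle), tolerance = 1e-10)
  # perfect single-predictor fit
  y1 <- matrix(rnorm(30), 30)
  expect_equal(rda_fit(y1, y1[, 1], n_perm = 0)$r2, 1, tolerance = 1e-12)
  # invariance to invertible linear recombination of X
  A <- matrix(c(2, 1, 0, 1, 3, 1, 0, 0, 1), 3)
  fit2 <- rda_fit(Y, X %*% A, n_perm = 0)
  expect_equal(fit$r2, fit2$r2, tolerance = 1e-10)
  expect_equal(fit$eigenvalues, fit2$eigenvalues, tolerance = 1e-10)
  # eigenvalues non-negative and non-increasing
  expect_true(all(diff(fit$eigenvalues) <= 1e-12))
  expect_true(all(fit$eigenvalues >= 0))
  # rank-deficient X warns
  expect_warning(rda_fit(Y, cbind(X, X[, 1] * 1), n_perm = 0),
                 "rank-deficient")
})

test_that("Ezekiel adjustment and VIF match their closed forms", {
  expect_equal(adjusted_r2(0.5, 40, 7), 1 - 0.5 * 39 / 32, tolerance = 1e-12)
  expect_equal(adjusted_r2(0.5, 40, 7), 0.390625)
  set.seed(3)
  z <- qr.Q(qr(scale(matrix(rnorm(200 * 2), 200), scale = FALSE)))
  x1 <- z[, 1]
  x2 <- 0.9 * z[, 1] + sqrt(1 - 0.81) * z[, 2]   # cor exactly 0.9
  v <- vif(cbind(x1 = x1, x2 = x2))
  expect_equal(unname(v), rep(1 / (1 - 0.81), 2), tolerance = 1e-10)
  expect_equal(unname(v)[1], 5.263, tolerance = 1e-3)
  # orthogonal predictors: VIF 1
  v0 <- vif(z)
  expect_equal(unname(v0), c(1, 1), tolerance = 1e-10)
  # exact collinearity: infinite
  expect_true(is.infinite(vif(cbind(a = x1, b = x1))[1]))
})

test_that("forward selection finds the true driver and prunes collinearity", {
  hits <- 0
  extras <- 0
  for (s in 1:20) {
    set.seed(s)
    n <- 30
    x1 <- rnorm(n)
    X <- cbind(x1 = x1, n1 = rnorm(n), n2 = rnorm(n))
    Y <- cbind(x1 * 2, -x1) + matrix(rnorm(2 * n, sd = 0.4), n)
    fs <- forward_select(Y, X, alpha = 0.05, n_perm = 199, seed = s)
    hits <- hits + (length(fs$selected) >= 1 && fs$selected[1] == "x1")
    extras <- extras + max(0, length(fs$selected) - 1)
  }
  expect_equal(hits, 20)          # the true driver always enters first
  expect_lte(extras, 3)           # noise enters only at ~the alpha rate
  # duplicate predictors: at most one survives VIF pruning
  set.seed(9)
  x <- rnorm(40)
  Xd <- cbind(a = x, b = x + rnorm(40, sd = 1e-4), c = rnorm(40))
  Yd <- cbind(x, x) + matrix(rnorm(80, sd = 0.2), 40)
  fsd <- forward_select(Yd, Xd, alpha = 0.05, n_perm = 199, seed = 2)
  expect_lte(sum(c("a", "b") %in% fsd$selected), 1)
  expect_true(all(fsd$vif <= 10))
})

test_that("with the entry test disabled all candidates enter by added R2", {
  set.seed(12)
  n <- 30
  X <- qr.Q(qr(scale(matrix(rnorm(n * 4), n),
                     scale = FALSE)))     # centered orthogonal candidates
  colnames(X) <- paste0("v", 1:4)
  Y <- matrix(rnorm(n * 3), n)
  fs <- forward_select(Y, X, alpha = 2, n_perm = 99, seed = 1)
  expect_setequal(fs$selected, colnames(X))
  expect_true(all(diff(fs$steps$added_r2) <= 1e-12))
})

test_that("coordinate projection approximates great-circle distances", {
  md <- data.frame(sample_id = c("a", "b"),
                   latitude = c(43, 44), longitude = c(116, 116))
  xy <- project_coordinates(md)
  expect_equal(as.numeric(dist(xy)), 6371 * pi / 180, tolerance = 1e-3)
  expect_equal(as.numeric(dist(xy)), 111.19, tolerance = 0.01)
  # identical positions project to the origin
  md0 <- data.frame(sample_id = c("a", "b"), latitude = c(43, 43),
                    longitude = c(116, 116))
  expect_equal(unname(project_coordinates(md0)), matrix(0, 2, 2))
  # against the haversine oracle over the survey extent (~470 km)
  set.seed(5)
  lon <- runif(15, 112.6, 116.9)
  lat <- runif(15, 42.2, 43.5)
  xy2 <- project_coordinates(data.frame(sample_id = paste0("s", 1:15),
                                        latitude = lat, longitude = lon))
  proj_d <- as.matrix(dist(xy2))
  hav_d <- outer(1:15, 1:15, function(i, j)
    haversine_km(lon[i], lat[i], lon[j], lat[j]))
  up <- upper.tri(proj_d)
  rel_err <- abs(proj_d[up] - hav_d[up]) / hav_d[up]
  expect_lt(max(rel_err), 0.01)
})

test_that("PCNM reduces to PCoA without truncation and is orthogonal", {
  set.seed(7)
  xy <- cbind(runif(12), runif(12))
  geo <- geographic_distance(xy)
  pc <- pcnm_axes(geo, truncation = max(as.matrix(geo)) + 1)
  cs <- cmdscale(as.matrix(geo), k = ncol(pc$vectors))
  expect_equal(abs(unname(pc$vectors)), abs(unname(cs)), tolerance = 1e-8)
  # centered, orthogonal columns
  pc2 <- pcnm_axes(geo)
  expect_lt(max(abs(colMeans(pc2$vectors))), 1e-8)
  gram <- crossprod(pc2$vectors)
  expect_lt(max(abs(gram[upper.tri(gram)])), 1e-8)
  expect_true(all(diff(pc2$values) <= 1e-12))
  expect_error(pcnm_axes(dist_matrix(matrix(0, 2, 2), "geographic")),
               "three")
})

test_that("the leading PCNM axis on a transect is a half-wave", {
  xy <- cbind(1:10, rep(0, 10))
  rownames(xy) <- paste0("p", 1:10)
  pc <- pcnm_axes(geographic_distance(xy))
  v <- pc$vectors[, 1]
  sign_changes <- sum(diff(sign(v[v != 0])) != 0)
  expect_equal(sign_changes, 1)
})

test_that("variation partitioning obeys inclusion-exclusion and orthogonality", {
  set.seed(31)
  Y <- matrix(rnorm(40 * 6), 40)
  E <- matrix(rnorm(40 * 2), 40)
  S <- matrix(rnorm(40 * 3), 40)
  T_ <- matrix(rnorm(40 * 2), 40)
  vp <- variation_partition(Y, E, S, T_, n_perm = 99, seed = 1)
  f <- vp$fractions
  expect_equal(unname(sum(f[1:7])), unname(f[["total_explained"]]),
               tolerance = 1e-10)
  expect_equal(unname(f[["total_explained"]] + f[["residual"]]), 1,
               tolerance = 1e-12)
  # single-set collapse
  vp1 <- variation_partition(Y, E = E, n_perm = 99, seed = 1)
  expect_equal(unname(vp1$fractions[["pure_E"]]),
               rda_fit(Y, E, n_perm = 0)$adj_r2, tolerance = 1e-12)
  # constructed orthogonal E and S with Y driven by E only
  pure_s <- shared_es <- numeric(10)
  for (s in 1:10) {
    set.seed(100 + s)
    q <- qr.Q(qr(matrix(rnorm(40 * 4), 40)))
    E2 <- q[, 1:2]
    S2 <- q[, 3:4]
    Y2 <- E2 %*% matrix(c(1, 0.5, -0.5, 1), 2) + matrix(rnorm(80, sd = 0.3), 40)
    vps <- variation_partition(Y2, E2, S2, n_perm = 99, seed = s)
    pure_s[s] <- vps$fractions[["pure_S"]]
    shared_es[s] <- vps$fractions[["shared_ES"]]
  }
  expect_lt(abs(mean(pure_s)), 0.02)
  expect_lt(abs(mean(shared_es)), 0.02)
  # overfit guard
  expect_error(variation_partition(Y, matrix(rnorm(40 * 39), 40)),
               "overfitted")
})

test_that("distance decay recovers an exact linear relationship", {
  set.seed(13)
  xy <- cbind(runif(12, 0, 50), runif(12, 0, 50))
  rownames(xy) <- paste0("s", 1:12)
  geo <- geographic_distance(xy)
  gm <- as.matrix(geo)
  sim_m <- 1 - 0.002 * gm
  diag(sim_m) <- 1
  sim <- dist_matrix(sim_m, "similarity")
  dd <- distance_decay(sim, geo, n_perm = 99, seed = 1)
  expect_equal(dd$slope, -0.002, tolerance = 1e-10)
  expect_equal(dd$r2, 1, tolerance = 1e-10)
  expect_equal(dd$p, perm_p <- 1 / 100)
  # relabeling invariance
  pm <- sample(12)
  sim_p <- dist_matrix(sim_m[pm, pm], "similarity")
  geo_p <- dist_matrix(gm[pm, pm], "geographic")
  dd2 <- distance_decay(sim_p, geo_p, n_perm = 99, seed = 1)
  expect_equal(dd2$slope, dd$slope, tolerance = 1e-12)
  # degenerate geography
  same <- dist_matrix(matrix(0, 3, 3), "geographic")
  ones <- dist_matrix(matrix(1, 3, 3), "similarity")
  expect_error(distance_decay(ones, same), "constant")
})
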