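# Abundance-based null model for beta-diversity and the stochasticity
# ratio (SR): how close observed pairwise community similarity lies to the
# expectation under a null that preserves each sample's richness and read
# total while randomizing which taxa occur and how reads fall on them.

#' Randomize a community table under the abundance-based null model
#'
#' For each sample with observed richness `s` and read total `N`, the null
#' draws `s` species without replacement with probability proportional to
#' their occupancy (number of samples in which they occur), seeds each
#' drawn species with one read, and distributes the remaining `N - s`
#' reads multinomially with probability proportional to the regional
#' relative abundance of the drawn species.  Per-sample richness and read
#' totals are preserved exactly.
#'
#' Two simpler randomizers are available for sensitivity analysis:
#' `"equiprobable"` draws species uniformly and fills reads uniformly;
#' `"shuffle"` permutes each sample's counts across the species pool.
#'
#' @param cm a preprocessed, rarefied [community_matrix()].
#' @param seed integer seed.
#' @param method `"occupancy_abundance"` (default), `"equiprobable"` or
#'   `"shuffle"`.
#' @return a randomized `community_matrix` with identical row sums and
#'   row richness.
#' @export
null_randomize <- function(cm, seed = 1,
                           method = c("occupancy_abundance", "equiprobable",
                                      "shuffle")) {
  stopifnot(inherits(cm, "community_matrix"))
  method <- match.arg(method)
  x <- cm$counts
  occupancy <- colSums(x > 0)
  pool <- which(occupancy > 0)
  regional <- colSums(x) / sum(x)
  out <- with_seed(seed, {
    res <- matrix(0L, nrow(x), ncol(x), dimnames = dimnames(x))
    for (i in seq_len(nrow(x))) {
      s_i <- sum(x[i, ] > 0)
      n_i <- sum(x[i, ])
      if (s_i > length(pool))
        stop("sample richness exceeds species pool size")
      if (method == "shuffle") {
        res[i, ] <- x[i, sample.int(ncol(x))]
        next
      }
      # weighted sampling without replacement via exponential keys
      # (Efraimidis-Spirakis): take the s_i smallest of Exp(1)/weight.
      prob <- if (method == "occupancy_abundance")
        occupancy[pool] else rep(1, length(pool))
      keys <- stats::rexp(length(pool)) / prob
      drawn <- pool[order(keys)[seq_len(s_i)]]
      fill_prob <- if (method == "occupancy_abundance")
        regional[drawn] else rep(1, length(drawn))
      if (sum(fill_prob) <= 0) fill_prob <- rep(1, length(drawn))
      extra <- as.vector(stats::rmultinom(1, n_i - s_i,
                                          fill_prob / sum(fill_prob)))
      res[i, drawn] <- 1L + extra
    }
    res
  })
  community_matrix(out, taxonomy = cm$taxonomy)
}

#' Null-model expectation of pairwise community similarity
#'
#' Repeats [null_randomize()] `n_rand` times and averages the Bray-Curtis
#' similarity (1 - dissimilarity) per sample pair, giving the matrix
#' `E_ij` of expected similarities under the null.  The per-pair
#' Monte-Carlo standard error is stored so that the adequacy of `n_rand`
#' can be judged.
#'
#' @param cm a preprocessed, rarefied [community_matrix()].
#' @param n_rand number of randomizations (default 1000, minimum 2).
#' @param seed integer master seed; randomization `k` uses a seed derived
#'   from it.
#' @param method randomizer passed to [null_randomize()].
#' @return an object of class `null_ensemble`: `expected` (a similarity
#'   `dist_matrix`), `se` (matrix of Monte-Carlo standard errors),
#'   `n_rand`, `seed`, `method`.
#' @export
expected_similarity <- function(cm, n_rand = 1000, seed = 1,
                                method = "occupancy_abundance") {
  stopifnot(inherits(cm, "community_matrix"))
  if (n_rand < 2) stop("n_rand must be at least 2")
  n <- nrow(cm$counts)
  mean_s <- matrix(0, n, n)
  m2 <- matrix(0, n, n)
  for (k in seq_len(n_rand)) {
    rnd <- null_randomize(cm, seed = derive_seed(seed, k), method = method)
    s <- 1 - as.matrix(vegan::vegdist(rnd$counts, method = "bray"))
    delta <- s - mean_s
    mean_s <- mean_s + delta / k
    m2 <- m2 + delta * (s - mean_s)
  }
  diag(mean_s) <- 1
  se <- sqrt(m2 / (n_rand - 1) / n_rand)
  diag(se) <- 0
  dimnames(se) <- dimnames(mean_s) <- list(sample_ids(cm), sample_ids(cm))
  structure(list(
    expected = dist_matrix(mean_s, kind = "similarity",
                           ids = sample_ids(cm)),
    se = se, n_rand = n_rand, seed = seed, method = method),
    class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("null ensemble: %d randomizations (%s), mean MC SE %.4f\n",
              x$n_rand, x$method, mean(x$se[upper.tri(x$se)])))
  invisible(x)
}

# Per-pair stochasticity: ratio of observed to expected similarity folded
# into (0, 1].  ST = E/C when C >= E (observed more similar than expected,
# deterministic convergence), C/E when C < E (deterministic divergence).
st_pair <- function(c_ij, e_ij) {
  if (c_ij == 0 && e_ij == 0) return(1)
  if (c_ij >= e_ij) e_ij / c_ij else c_ij / e_ij
}

#' Stochasticity ratio per habitat group
#'
#' Compares the observed pairwise similarity matrix `C` with the null
#' expectation `E`: the per-pair stochasticity `ST_ij` is the ratio of the
#' smaller to the larger of the two (1 when they agree exactly; 0 when the
#' observed similarity is 0 but the null expects overlap).  The group SR
#' is 100 times the mean `ST` over within-group pairs: high SR means the
#' observed structure is close to the null (stochastic assembly), low SR
#' means strong departure (deterministic assembly).  Group differences are
#' assessed by pairwise two-sided Wilcoxon rank-sum tests on the
#' within-group ST values with BH correction and a compact-letter display.
#'
#' @param c_sim observed similarity `dist_matrix` (1 - Bray-Curtis).
#' @param ens a `null_ensemble` from [expected_similarity()] (or a
#'   similarity `dist_matrix` of expectations).
#' @param groups group label per sample.
#' @param alpha level for the compact letters (default 0.01).
#' @return an object of class `stochasticity_result`: `st` (pairwise ST
#'   matrix), `sr` (named per-group SR, percent), `sr_overall`, `letters`,
#'   `pairwise_p`, `per_pair` (long data.frame of within-group pairs).
#' @export
stochasticity_ratio <- function(c_sim, ens, groups, alpha = 0.01) {
  stopifnot(inherits(c_sim, "dist_matrix"))
  e_mat <- if (inherits(ens, "null_ensemble")) as.matrix(ens$expected)
           else as.matrix(ens)
  c_mat <- as.matrix(c_sim)
  if (!identical(dim(c_mat), dim(e_mat))) stop("matched samples required")
  n <- nrow(c_mat)
  if (length(groups) != n) stop("groups must match samples")
  groups <- as.character(groups)
  st <- matrix(1, n, n, dimnames = dimnames(c_mat))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      st[i, j] <- st[j, i] <- st_pair(c_mat[i, j], e_mat[i, j])
    }
  }
  lv <- unique(groups)
  within_vals <- lapply(lv, function(g) {
    idx <- which(groups == g)
    sub <- st[idx, idx, drop = FALSE]
    sub[upper.tri(sub)]
  })
  names(within_vals) <- lv
  sr <- vapply(within_vals, function(v)
    if (length(v)) 100 * mean(v) else NA_real_, numeric(1))
  all_within <- unlist(within_vals)
  k <- length(lv)
  pm <- NULL
  lets <- stats::setNames(rep("a", k), lv)
  if (k >= 2 && all(lengths(within_vals) >= 2)) {
    pm <- matrix(NA_real_, k, k, dimnames = list(lv, lv))
    idx <- which(upper.tri(pm), arr.ind = TRUE)
    pr <- numeric(nrow(idx))
    for (r in seq_len(nrow(idx))) {
      pr[r] <- suppressWarnings(stats::wilcox.test(
        within_vals[[idx[r, 1]]], within_vals[[idx[r, 2]]]))$p.value
    }
    pr <- bh_adjust(pr)
    for (r in seq_len(nrow(idx))) {
      pm[idx[r, 1], idx[r, 2]] <- pm[idx[r, 2], idx[r, 1]] <- pr[r]
    }
    lets <- compact_letters(pm, alpha)
  }
  pairs <- do.call(rbind, lapply(lv, function(g) {
    idx <- which(groups == g)
    if (length(idx) < 2) return(NULL)
    cmb <- utils::combn(idx, 2)
    data.frame(group = g,
               sample_1 = rownames(st)[cmb[1, ]],
               sample_2 = rownames(st)[cmb[2, ]],
               observed = c_mat[t(cmb)],
               expected = e_mat[t(cmb)],
               st = st[t(cmb)])
  }))
  structure(list(st = st, sr = sr,
                 sr_overall = 100 * mean(all_within),
                 letters = lets, pairwise_p = pm, per_pair = pairs,
                 alpha = alpha),
            class = "stochasticity_result")
}

#' @export
print.stochasticity_result <- function(x, ...) {
  cat("stochasticity ratio (SR, % of null expectation):\n")
  print(round(x$sr, 1))
  cat("letters (alpha =", x$alpha, "):",
      paste(names(x$letters), x$letters, sep = "=", collapse = "  "), "\n")
  cat(sprintf("overall SR = %.1f%%\n", x$sr_overall))
  invisible(x)
}

#' Assembly significance against randomized datasets
#'
#' Tests whether the observed group structure exceeds what the null model
#' produces: the observed PERMANOVA pseudo-F (Bray-Curtis on the observed
#' table) is compared with the pseudo-F recomputed on each of `n_rand`
#' randomized tables; `p = (count(F_null >= F_obs) + 1)/(n_rand + 1)`.
#'
#' @param cm a preprocessed, rarefied [community_matrix()].
#' @param groups group label per sample.
#' @param n_rand number of randomized datasets (default 1000).
#' @param seed integer seed.
#' @param method randomizer passed to [null_randomize()].
#' @return list with `f_obs`, `f_null` (vector), `p`.
#' @export
assembly_significance <- function(cm, groups, n_rand = 1000, seed = 1,
                                  method = "occupancy_abundance") {
  stopifnot(inherits(cm, "community_matrix"))
  f_of <- function(tab) {
    d <- dist_matrix(vegan::vegdist(tab, method = "bray"),
                     kind = "dissimilarity", ids = rownames(tab))
    permanova_test(d, groups, n_perm = 0, seed = 1)$statistic
  }
  f_obs <- f_of(cm$counts)
  f_null <- vapply(seq_len(n_rand), function(k) {
    rnd <- null_randomize(cm, seed = derive_seed(seed, 100000 + k),
                          method = method)
    f_of(rnd$counts)
  }, numeric(1))
  list(f_obs = f_obs, f_null = f_null,
       p = perm_pval(sum(f_null >= f_obs), n_rand))
}
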