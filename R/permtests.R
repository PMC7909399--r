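# Permutation tests on distance matrices and group comparisons: Mantel,
# ANOSIM, PERMANOVA, Kruskal-Wallis with compact letters, and a
# permutation difference-of-means test for relative abundances.

#' Mantel test between two distance matrices
#'
#' Correlation (Spearman by default, with average ranks on ties) between
#' the upper-triangle entries of two matched distance matrices.  The null
#' distribution is obtained by simultaneous row/column permutation of
#' `d2`; the p-value is one-sided upper, `(count >= r + 1)/(n_perm + 1)`.
#'
#' @param d1,d2 `dist_matrix` objects over the same samples in the same
#'   order.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param n_perm number of permutations (default 9999).
#' @param seed integer seed.
#' @return list with `statistic` (Mantel r), `p`, `n_perm`, `method`.
#' @export
mantel_test <- function(d1, d2, method = c("spearman", "pearson"),
                        n_perm = 9999, seed = 1) {
  method <- match.arg(method)
  m1 <- as.matrix(d1)
  m2 <- as.matrix(d2)
  if (!identical(dim(m1), dim(m2)))
    stop("distance matrices differ in size")
  n <- nrow(m1)
  up <- upper.tri(m1)
  v1 <- m1[up]
  if (method == "spearman") {
    v1 <- rank(v1)
    rk2 <- matrix(0, n, n)
    rk2[up] <- rank(m2[up])
    rk2 <- rk2 + t(rk2)
    m2v <- rk2
  } else {
    m2v <- m2
  }
  r_obs <- stats::cor(v1, m2v[up])
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      pm <- sample.int(n)
      stats::cor(v1, m2v[pm, pm][up]) >= r_obs - 1e-12
    }, logical(1)))
  })
  list(statistic = r_obs, p = perm_pval(exceed, n_perm), n_perm = n_perm,
       method = method, seed = seed)
}

#' Analysis of similarity (ANOSIM)
#'
#' Ranks all pairwise dissimilarities (average ranks on ties) and computes
#' `R = (mean between-group rank - mean within-group rank) / (M / 2)` with
#' `M = n (n - 1) / 2`.  `R = 1` indicates complete group separation,
#' values near 0 no separation.  The p-value is one-sided upper over
#' group-label permutations.
#'
#' @param d a `dist_matrix` of kind `"dissimilarity"`.
#' @param groups group label per sample; at least two groups of two.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @return list with `statistic` (ANOSIM R), `p`, `n_perm`.
#' @export
anosim_test <- function(d, groups, n_perm = 999, seed = 1) {
  m <- as.matrix(d)
  n <- nrow(m)
  groups <- as.character(groups)
  if (length(groups) != n) stop("groups must match samples")
  tb <- table(groups)
  if (length(tb) < 2) stop("need at least two groups")
  if (any(tb < 2)) stop("every group needs at least two samples")
  up <- upper.tri(m)
  rk <- matrix(0, n, n)
  rk[up] <- rank(m[up])
  rk <- rk + t(rk)
  big_m <- n * (n - 1) / 2
  r_for <- function(g) {
    same <- outer(g, g, "==")[up]
    (mean(rk[up][!same]) - mean(rk[up][same])) / (big_m / 2)
  }
  r_obs <- r_for(groups)
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      r_for(groups[sample.int(n)]) >= r_obs - 1e-12
    }, logical(1)))
  })
  list(statistic = r_obs, p = perm_pval(exceed, n_perm), n_perm = n_perm,
       seed = seed)
}

#' One-way PERMANOVA on a distance matrix
#'
#' Partitions the sum of squared inter-point distances among groups:
#' `SS_total = (1/n) sum_{i<j} d_ij^2`,
#' `SS_within = sum_g (1/n_g) sum_{i<j in g} d_ij^2`, and
#' `pseudo-F = ((SS_total - SS_within)/(a - 1)) / (SS_within/(n - a))`.
#' Significance by group-label permutation (upper tail).
#'
#' @param d a `dist_matrix` of kind `"dissimilarity"`.
#' @param groups group label per sample.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @return list with `statistic` (pseudo-F), `r2`, `p`, `df`, `n_perm`.
#' @export
permanova_test <- function(d, groups, n_perm = 999, seed = 1) {
  m <- as.matrix(d)
  n <- nrow(m)
  groups <- as.character(groups)
  if (length(groups) != n) stop("groups must match samples")
  tb <- table(groups)
  if (length(tb) < 2) stop("need at least two groups")
  if (any(tb < 2)) stop("every group needs at least two samples")
  d2 <- m^2
  ss_total <- sum(d2[upper.tri(d2)]) / n
  if (ss_total <= 0) stop("degenerate distances: all samples identical")
  a <- length(tb)
  ss_within_for <- function(g) {
    s <- 0
    for (lev in unique(g)) {
      idx <- which(g == lev)
      s <- s + sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
    }
    s
  }
  f_for <- function(g) {
    ssw <- ss_within_for(g)
    ((ss_total - ssw) / (a - 1)) / (ssw / (n - a))
  }
  f_obs <- f_for(groups)
  ssw_obs <- ss_within_for(groups)
  if (n_perm == 0) {
    return(list(statistic = f_obs, r2 = 1 - ssw_obs / ss_total, p = NA_real_,
                df = c(a - 1, n - a), n_perm = 0L, seed = seed))
  }
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      f_for(groups[sample.int(n)]) >= f_obs - 1e-12
    }, logical(1)))
  })
  list(statistic = f_obs, r2 = 1 - ssw_obs / ss_total,
       p = perm_pval(exceed, n_perm), df = c(a - 1, n - a),
       n_perm = n_perm, seed = seed)
}

#' Kruskal-Wallis test with compact letter display
#'
#' Tie-corrected Kruskal-Wallis H across groups; when significant at
#' `alpha`, pairwise two-sided Wilcoxon rank-sum tests with
#' Benjamini-Hochberg correction feed a compact-letter display (groups
#' sharing a letter are not significantly different).
#'
#' @param values numeric vector, one value per sample.
#' @param groups group label per sample.
#' @param alpha significance level (default 0.05).
#' @return list with `H`, `p`, `letters` (named by group), `pairwise`
#'   (matrix of BH-adjusted p-values, `NULL` when the omnibus test is not
#'   significant).
#' @export
kruskal_letters <- function(values, groups, alpha = 0.05) {
  groups <- as.character(groups)
  if (length(values) != length(groups)) stop("length mismatch")
  tb <- table(groups)
  if (any(tb == 0) || length(tb) < 2) stop("need two non-empty groups")
  lv <- names(tb)
  if (stats::sd(values) == 0) {
    # degenerate all-ties case: no evidence of any difference
    return(list(H = 0, p = 1,
                letters = stats::setNames(rep("a", length(lv)), lv),
                pairwise = NULL))
  }
  kw <- stats::kruskal.test(values, factor(groups))
  if (is.na(kw$p.value) || kw$p.value >= alpha) {
    return(list(H = unname(kw$statistic), p = kw$p.value,
                letters = stats::setNames(rep("a", length(lv)), lv),
                pairwise = NULL))
  }
  k <- length(lv)
  pm <- matrix(NA_real_, k, k, dimnames = list(lv, lv))
  pr <- c()
  idx <- which(upper.tri(pm), arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]
    w <- suppressWarnings(stats::wilcox.test(values[groups == lv[i]],
                                             values[groups == lv[j]]))
    pr <- c(pr, w$p.value)
  }
  pr <- bh_adjust(pr)
  for (r in seq_len(nrow(idx))) {
    pm[idx[r, 1], idx[r, 2]] <- pm[idx[r, 2], idx[r, 1]] <- pr[r]
  }
  list(H = unname(kw$statistic), p = kw$p.value,
       letters = compact_letters(pm, alpha), pairwise = pm)
}

#' Two-group permutation test on mean relative abundance
#'
#' Non-parametric two-sided test for a difference in group mean
#' proportions: the statistic is the difference of group means, the null
#' distribution comes from reassigning sample labels.  All arrangements
#' are enumerated when there are at most `max_exact` of them, otherwise
#' `n_perm` random reassignments are drawn.  With zero variance in the
#' pooled data the test is degenerate and `p = 1` by convention.
#'
#' @param x,y per-sample relative abundances in the two groups (each of
#'   length >= 2).
#' @param n_perm permutations when sampling (default 9999).
#' @param max_exact enumerate exhaustively when `choose(n, n_x)` is at
#'   most this (default 10000).
#' @param seed integer seed.
#' @return list with `statistic` (mean(x) - mean(y)), `p`, `exact`,
#'   `n_perm`.
#' @export
whites_test <- function(x, y, n_perm = 9999, max_exact = 10000, seed = 1) {
  if (length(x) < 2 || length(y) < 2)
    stop("both groups need at least two samples")
  pooled <- c(x, y)
  d_obs <- mean(x) - mean(y)
  if (stats::sd(pooled) == 0) {
    return(list(statistic = d_obs, p = 1, exact = TRUE, n_perm = 0))
  }
  n <- length(pooled)
  n1 <- length(x)
  n_arr <- choose(n, n1)
  tol <- 1e-12
  if (n_arr <= max_exact) {
    combs <- utils::combn(n, n1)
    diffs <- apply(combs, 2, function(idx) {
      mean(pooled[idx]) - mean(pooled[-idx])
    })
    p <- mean(abs(diffs) >= abs(d_obs) - tol)
    return(list(statistic = d_obs, p = p, exact = TRUE,
                n_perm = ncol(combs)))
  }
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(n, n1)
      abs(mean(pooled[idx]) - mean(pooled[-idx])) >= abs(d_obs) - tol
    }, logical(1)))
  })
  list(statistic = d_obs, p = perm_pval(exceed, n_perm), exact = FALSE,
       n_perm = n_perm)
}
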