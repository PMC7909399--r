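# Constrained ordination and spatial analysis: Hellinger transform, RDA
# with a permutation global test, permutation-based forward selection with
# VIF pruning, geographic projection, PCNM spatial eigenfunctions,
# three-set variation partitioning by partial RDA, distance-decay fits.

#' Hellinger transform of a community table
#'
#' Square root of relative abundances: `y'_ij = sqrt(y_ij / rowsum_i)`.
#' Each transformed row has unit sum of squares, making the table suitable
#' for Euclidean-based ordination.  Wraps [vegan::decostand()].
#'
#' @param cm a [community_matrix()] or abundance matrix with positive row
#'   sums.
#' @return a numeric matrix of the same shape.
#' @export
hellinger <- function(cm) {
  x <- if (inherits(cm, "community_matrix")) cm$counts else as.matrix(cm)
  if (any(rowSums(x) == 0)) stop("zero row sum: cannot Hellinger-transform")
  out <- as.matrix(vegan::decostand(x, method = "hellinger"))
  attr(out, "parameters") <- NULL
  attr(out, "decostand") <- NULL
  out
}

#' Ezekiel-adjusted R-squared
#'
#' `1 - (1 - R2) (n - 1) / (n - m - 1)`, the adjustment used throughout
#' variation partitioning.
#'
#' @param r2 unadjusted R-squared.
#' @param n number of observations.
#' @param m number of (independent) predictors.
#' @return adjusted R-squared (may be negative).
#' @export
adjusted_r2 <- function(r2, n, m) 1 - (1 - r2) * (n - 1) / (n - m - 1)

# Standardize columns to zero mean / unit variance; constant columns error.
std_cols <- function(X, what = "predictor") {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("constant ", what, " column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  scale(X)
}

#' Redundancy analysis with a permutation global test
#'
#' Least-squares fit of a (column-centered) multivariate response on a
#' standardized predictor matrix; canonical axes are the principal axes of
#' the fitted values.  With a conditioning matrix `Z` the fit is partial
#' (both `Y` and `X` are residualized on `Z` first).  Significance of the
#' constrained variation is assessed by permuting response rows (residual
#' rows of the reduced model when `Z` is given), with
#' `p = (count >= observed + 1) / (n_perm + 1)`.
#'
#' @param Y response matrix (e.g. Hellinger-transformed counts); centered
#'   internally.
#' @param X predictor matrix or data.frame; standardized internally.
#' @param Z optional conditioning (covariable) matrix, standardized
#'   internally.
#' @param n_perm number of permutations for the global test (0 skips it).
#' @param seed integer seed for the permutations.
#' @param standardize standardize `X` (and `Z`)?  Disable only when columns
#'   are already comparable.
#' @return an object of class `rda_result`: eigenvalues, site scores,
#'   predictor scores, `r2`, `adj_r2`, `pseudo_f`, `p`, and the fit's
#'   sums of squares.
#' @export
rda_fit <- function(Y, X, Z = NULL, n_perm = 999, seed = 1,
                    standardize = TRUE) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  Yc <- sweep(Y, 2, colMeans(Y))
  Xs <- if (standardize) std_cols(X) else {
    X <- as.matrix(X); scale(X, center = TRUE, scale = FALSE)
  }
  if (nrow(Xs) != n) stop("X and Y must have the same number of rows")
  q <- 0L
  Yr <- Yc
  Xr <- Xs
  if (!is.null(Z)) {
    Zs <- if (standardize) std_cols(Z, "covariable") else
      scale(as.matrix(Z), center = TRUE, scale = FALSE)
    qz <- qr(Zs)
    q <- qz$rank
    Yr <- Yc - qr.fitted(qz, Yc)
    Xr <- Xs - qr.fitted(qz, Xs)
  }
  qrx <- qr(Xr)
  m <- qrx$rank
  if (m < ncol(Xr))
    warning("rank-deficient predictor matrix; using least-norm fit (rank ",
            m, " of ", ncol(Xr), ")")
  if (n <= m + q + 1) stop("too few samples for ", m + q, " predictors")
  fitted <- qr.fitted(qrx, Yr)
  ss_tot <- sum(Yc^2)
  ss_fit <- sum(fitted^2)
  ss_res <- sum((Yr - fitted)^2)
  r2 <- ss_fit / ss_tot
  f_stat <- (ss_fit / m) / (ss_res / (n - m - q - 1))
  p <- NA_real_
  if (n_perm > 0) {
    exceed <- with_seed(seed, {
      sum(vapply(seq_len(n_perm), function(i) {
        Yp <- Yr[sample.int(n), , drop = FALSE]
        fp <- qr.fitted(qrx, Yp)
        sfp <- sum(fp^2)
        (sfp / m) / ((sum(Yp^2) - sfp) / (n - m - q - 1)) >= f_stat
      }, logical(1)))
    })
    p <- perm_pval(exceed, n_perm)
  }
  sv <- svd(fitted)
  pos <- sv$d^2 > max(sv$d^2, .Machine$double.eps) * 1e-12
  eig <- sv$d[pos]^2 / (n - 1)
  site_scores <- sv$u[, pos, drop = FALSE] %*% diag(sv$d[pos],
                                                    nrow = sum(pos))
  rownames(site_scores) <- rownames(Y)
  pred_scores <- suppressWarnings(stats::cor(Xr, site_scores))
  structure(list(eigenvalues = eig, site_scores = site_scores,
                 predictor_scores = pred_scores, r2 = r2,
                 adj_r2 = adjusted_r2(r2, n, m), pseudo_f = f_stat, p = p,
                 ss_fit = ss_fit, ss_res = ss_res, ss_total = ss_tot,
                 n = n, m = m, q = q, fitted = fitted),
            class = "rda_result")
}

#' @export
print.rda_result <- function(x, ...) {
  cat(sprintf(
    "RDA: n = %d, m = %d%s | R2 = %.4f (adj %.4f), pseudo-F = %.3f, p = %s\n",
    x$n, x$m, if (x$q > 0) paste0(" (conditioned on ", x$q, ")") else "",
    x$r2, x$adj_r2, x$pseudo_f,
    if (is.na(x$p)) "NA" else format(x$p, digits = 4)))
  invisible(x)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` comes from regressing predictor
#' `j` on all others.  Exact collinearity is reported as `Inf`.
#'
#' @param X predictor matrix with at least two columns of nonzero variance.
#' @return named numeric vector of VIFs (all `>= 1`).
#' @export
vif <- function(X) {
  X <- std_cols(X)
  if (ncol(X) < 2) stop("need at least two predictors")
  vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum(X[, j]^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1), USE.NAMES = FALSE) |> stats::setNames(colnames(X))
}

#' Permutation-based forward selection of RDA predictors
#'
#' Greedy selection: at each step the candidate adding the most explained
#' variance (R-squared) enters, provided its partial permutation test
#' (conditioning on the variables already selected) gives `p < alpha`.
#' With `double_stop = TRUE`, selection additionally halts once the
#' cumulative adjusted R-squared would exceed that of the full model.
#' After selection, the variable with the largest VIF is dropped
#' iteratively until all retained VIFs fall at or below `vif_threshold`.
#'
#' @param Y response matrix (e.g. Hellinger-transformed counts).
#' @param X_all candidate predictor matrix or data.frame.
#' @param alpha significance level for entry (default 0.05).
#' @param n_perm permutations per entry test (default 999).
#' @param vif_threshold retained predictors must have VIF at or below this
#'   (default 10).
#' @param double_stop also stop when cumulative adjusted R2 exceeds the
#'   global model's (off by default).
#' @param seed integer seed.
#' @return an object of class `selection_trace`: `selected` (character),
#'   `steps` (data.frame variable/added_r2/cum_r2/p), `dropped_vif`,
#'   `vif` (post-pruning VIFs), `global_adj_r2`.
#' @export
forward_select <- function(Y, X_all, alpha = 0.05, n_perm = 999,
                           vif_threshold = 10, double_stop = FALSE,
                           seed = 1) {
  X_all <- as.matrix(X_all)
  if (is.null(colnames(X_all)))
    colnames(X_all) <- paste0("x", seq_len(ncol(X_all)))
  if (ncol(X_all) < 1) stop("need at least one candidate")
  Y <- as.matrix(Y)
  global_adj <- rda_fit(Y, X_all, n_perm = 0)$adj_r2
  selected <- character(0)
  steps <- list()
  step_i <- 0L
  remaining <- colnames(X_all)
  repeat {
    if (!length(remaining)) break
    cur <- if (length(selected))
      X_all[, selected, drop = FALSE] else NULL
    base_r2 <- if (length(selected))
      rda_fit(Y, cur, n_perm = 0)$r2 else 0
    added <- vapply(remaining, function(v) {
      rda_fit(Y, X_all[, c(selected, v), drop = FALSE], n_perm = 0)$r2 -
        base_r2
    }, numeric(1))
    best <- remaining[which.max(added)]
    step_i <- step_i + 1L
    fit <- rda_fit(Y, X_all[, best, drop = FALSE], Z = cur,
                   n_perm = n_perm, seed = derive_seed(seed, step_i))
    cum_r2 <- base_r2 + added[best]
    if (is.na(fit$p) || fit$p >= alpha) break
    if (double_stop &&
        adjusted_r2(cum_r2, nrow(Y), length(selected) + 1) > global_adj)
      break
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
    steps[[length(steps) + 1]] <- data.frame(
      variable = best, added_r2 = unname(added[best]),
      cum_r2 = unname(cum_r2), p = fit$p)
  }
  dropped <- character(0)
  while (length(selected) >= 2) {
    v <- vif(X_all[, selected, drop = FALSE])
    if (max(v) <= vif_threshold) break
    worst <- names(v)[which.max(v)]
    dropped <- c(dropped, worst)
    selected <- setdiff(selected, worst)
  }
  final_vif <- if (length(selected) >= 2)
    vif(X_all[, selected, drop = FALSE])
  else stats::setNames(rep(1, length(selected)), selected)
  structure(list(
    selected = selected,
    steps = if (length(steps)) do.call(rbind, steps) else
      data.frame(variable = character(0), added_r2 = numeric(0),
                 cum_r2 = numeric(0), p = numeric(0)),
    dropped_vif = dropped, vif = final_vif, global_adj_r2 = global_adj),
    class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat("forward selection:", if (length(x$selected))
    paste(x$selected, collapse = " + ") else "(none)", "\n")
  if (nrow(x$steps)) print(x$steps, row.names = FALSE)
  if (length(x$dropped_vif))
    cat("dropped by VIF pruning:", paste(x$dropped_vif, collapse = ", "),
        "\n")
  invisible(x)
}

#' Project geographic coordinates to planar kilometres
#'
#' Local equirectangular projection about the centroid:
#' `x = R dlon cos(lat0)`, `y = R dlat` (radians, `R = 6371` km).
#' Pairwise Euclidean distances then approximate great-circle distances
#' over regional extents.
#'
#' @param md metadata data.frame with `latitude` and `longitude` columns
#'   (decimal degrees), or a two-column matrix `(longitude, latitude)`.
#' @return matrix with columns `x`, `y` in km (centroid at the origin).
#' @export
project_coordinates <- function(md) {
  if (is.data.frame(md)) {
    lat <- md$latitude; lon <- md$longitude
    ids <- md$sample_id %||% rownames(md)
  } else {
    lon <- md[, 1]; lat <- md[, 2]; ids <- rownames(md)
  }
  r_earth <- 6371
  lat0 <- mean(lat) * pi / 180
  lon0 <- mean(lon)
  xy <- cbind(x = r_earth * (lon - lon0) * pi / 180 * cos(lat0),
              y = r_earth * (lat - mean(lat)) * pi / 180)
  rownames(xy) <- ids
  xy
}

#' Geographic distance matrix from projected coordinates
#' @param xy matrix from [project_coordinates()].
#' @return a `dist_matrix` of kind `"geographic"` (km).
#' @export
geographic_distance <- function(xy) {
  dist_matrix(stats::dist(xy), kind = "geographic", ids = rownames(xy))
}

#' PCNM spatial eigenfunctions
#'
#' Principal coordinates of neighbour matrices: the geographic distance
#' matrix is truncated at `t` (by default the longest edge of its minimum
#' spanning tree), distances beyond `t` are replaced by `4 t`, the matrix
#' `-d^2 / 2` is Gower double-centered and eigen-decomposed, and the axes
#' with positive eigenvalues are retained, each scaled by the square root
#' of its eigenvalue.  With no distance exceeding `t` this reduces to
#' metric PCoA.
#'
#' @param geo a `dist_matrix` of kind `"geographic"` (or any distances).
#' @param truncation optional truncation threshold; default = longest
#'   minimum-spanning-tree edge.
#' @param positive_moran keep only axes with positive Moran's I (relative
#'   to the within-threshold neighbour graph)?  Off by default.
#' @return an object of class `pcnm_basis`: `vectors` (samples x axes,
#'   centered, orthogonal), `values` (positive eigenvalues, decreasing),
#'   `threshold`, and `moran` when computed.
#' @export
pcnm_axes <- function(geo, truncation = NULL, positive_moran = FALSE) {
  d <- as.matrix(geo)
  n <- nrow(d)
  if (n < 3) stop("PCNM needs at least three samples")
  if (is.null(truncation)) {
    st <- vegan::spantree(stats::as.dist(d))
    truncation <- max(st$dist)
  }
  dtr <- ifelse(d > truncation, 4 * truncation, d)
  diag(dtr) <- 0
  a <- -0.5 * dtr^2
  g <- sweep(sweep(a, 1, rowMeans(a)), 2, colMeans(a)) + mean(a)
  eg <- eigen((g + t(g)) / 2, symmetric = TRUE)
  tol <- max(abs(eg$values)) * 1e-10
  pos <- eg$values > tol
  vals <- eg$values[pos]
  vecs <- eg$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(vals), nrow = length(vals))
  rownames(vecs) <- rownames(d)
  colnames(vecs) <- paste0("PCNM", seq_len(ncol(vecs)))
  moran <- NULL
  if (positive_moran || TRUE) {
    w <- (d <= truncation & d > 0) * 1
    sw <- sum(w)
    moran <- vapply(seq_len(ncol(vecs)), function(j) {
      v <- vecs[, j] - mean(vecs[, j])
      (n / sw) * as.numeric(t(v) %*% w %*% v) / sum(v^2)
    }, numeric(1))
    names(moran) <- colnames(vecs)
  }
  if (positive_moran) {
    keep <- moran > -1 / (n - 1)
    vecs <- vecs[, keep, drop = FALSE]
    vals <- vals[keep]
    moran <- moran[keep]
  }
  structure(list(vectors = vecs, values = vals, threshold = truncation,
                 moran = moran),
            class = "pcnm_basis")
}

#' @export
print.pcnm_basis <- function(x, ...) {
  cat(sprintf("PCNM basis: %d axes (truncation %.3f)\n",
              ncol(x$vectors), x$threshold))
  invisible(x)
}

#' Three-set variation partitioning by partial RDA
#'
#' Decomposes the explained (adjusted R-squared) variation of `Y` among up
#' to three explanatory sets -- environment `E`, spatial eigenfunctions
#' `S`, linear trend `T` -- into pure and shared fractions by
#' inclusion-exclusion over RDA fits on all non-empty subsets.  Pure
#' fractions are tested by permutation of the reduced-model residuals
#' (partial RDA).  Shared fractions can be negative: adjusted R-squared
#' arithmetic, not variance components.
#'
#' @param Y response matrix.
#' @param E,S,T_ explanatory matrices (any may be `NULL`); `S` may be a
#'   `pcnm_basis`.
#' @param n_perm permutations for the testable fractions.
#' @param seed integer seed.
#' @return an object of class `partition_fractions`: `fractions` (named:
#'   `pure_E`, `pure_S`, `pure_T`, `shared_ES`, `shared_ET`, `shared_ST`,
#'   `shared_EST`, `total_explained`, `residual`), `adj_r2` per subset,
#'   `tests` (pure-fraction permutation pseudo-F and p).
#' @export
variation_partition <- function(Y, E = NULL, S = NULL, T_ = NULL,
                                n_perm = 999, seed = 1) {
  if (inherits(S, "pcnm_basis")) S <- S$vectors
  sets <- Filter(Negate(is.null), list(E = E, S = S, T = T_))
  sets <- lapply(sets, as.matrix)
  if (!length(sets)) stop("no explanatory set supplied")
  Y <- as.matrix(Y)
  n <- nrow(Y)
  if (any(vapply(sets, nrow, 1L) != n)) stop("matrices are not row-aligned")
  if (sum(vapply(sets, ncol, 1L)) >= n - 1)
    stop("overfitted partition: combined predictor count >= n - 1")
  nm <- names(sets)
  subsets <- unlist(lapply(seq_along(nm), function(k)
    utils::combn(nm, k, simplify = FALSE)), recursive = FALSE)
  adj <- vapply(subsets, function(ss) {
    rda_fit(Y, do.call(cbind, sets[ss]), n_perm = 0)$adj_r2
  }, numeric(1))
  names(adj) <- vapply(subsets, paste, "", collapse = "")
  full <- adj[[paste(nm, collapse = "")]]
  frac <- c(pure_E = NA_real_, pure_S = NA_real_, pure_T = NA_real_,
            shared_ES = NA_real_, shared_ET = NA_real_, shared_ST = NA_real_,
            shared_EST = NA_real_)
  if (length(sets) == 3) {
    a <- full - adj[["ST"]]; b <- full - adj[["ET"]]; c_ <- full - adj[["ES"]]
    d <- full - adj[["T"]] - a - b
    e <- full - adj[["E"]] - b - c_
    f <- full - adj[["S"]] - a - c_
    g <- full - a - b - c_ - d - e - f
    frac[] <- c(a, b, c_, d, e, f, g)
  } else if (length(sets) == 2) {
    p1 <- full - adj[[nm[2]]]
    p2 <- full - adj[[nm[1]]]
    frac[paste0("pure_", nm[1])] <- p1
    frac[paste0("pure_", nm[2])] <- p2
    frac[paste0("shared_", paste(sort(nm), collapse = ""))] <- full - p1 - p2
  } else {
    frac[paste0("pure_", nm)] <- full
  }
  tests <- lapply(seq_along(nm), function(i) {
    others <- if (length(nm) > 1) do.call(cbind, sets[nm[-i]]) else NULL
    fit <- rda_fit(Y, sets[[nm[i]]], Z = others, n_perm = n_perm,
                   seed = derive_seed(seed, i))
    data.frame(fraction = paste0("pure_", nm[i]), pseudo_f = fit$pseudo_f,
               p = fit$p)
  })
  structure(list(
    fractions = c(frac, total_explained = unname(full),
                  residual = unname(1 - full)),
    adj_r2 = adj, tests = do.call(rbind, tests)),
    class = "partition_fractions")
}

#' @export
print.partition_fractions <- function(x, ...) {
  cat("variation partitioning (adjusted R2 fractions):\n")
  print(round(x$fractions, 4))
  print(x$tests, row.names = FALSE)
  invisible(x)
}

#' Distance-decay regression of community similarity on geographic distance
#'
#' Ordinary least squares of pairwise similarity on pairwise geographic
#' distance over the upper-triangle sample pairs; significance by
#' Mantel-style simultaneous row/column permutation of one matrix
#' (two-sided on the correlation).
#'
#' @param comm_sim a `dist_matrix` of kind `"similarity"`.
#' @param geo a `dist_matrix` of kind `"geographic"`, same samples.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return list with `slope`, `intercept`, `r2`, `r`, `p`, `n_pairs`.
#' @export
distance_decay <- function(comm_sim, geo, n_perm = 999, seed = 1) {
  stopifnot(inherits(comm_sim, "dist_matrix"), inherits(geo, "dist_matrix"))
  if (!identical(dim(as.matrix(comm_sim)), dim(as.matrix(geo))))
    stop("matched sample sets required")
  sm <- as.matrix(comm_sim)
  gm <- as.matrix(geo)
  n <- nrow(sm)
  up <- upper.tri(sm)
  y <- sm[up]
  x <- gm[up]
  if (stats::sd(x) == 0) stop("constant geographic distance")
  fit <- stats::lm.fit(cbind(1, x), y)
  slope <- fit$coefficients[2]
  intercept <- fit$coefficients[1]
  r_obs <- stats::cor(x, y)
  r2 <- r_obs^2
  exceed <- with_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      pm <- sample.int(n)
      abs(stats::cor(x, sm[pm, pm][up])) >= abs(r_obs) - 1e-12
    }, logical(1)))
  })
  list(slope = unname(slope), intercept = unname(intercept),
       r2 = unname(r2), r = unname(r_obs),
       p = perm_pval(exceed, n_perm), n_pairs = length(y))
}
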