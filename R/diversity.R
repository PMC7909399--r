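# Alpha diversity, rarefaction curves, Bray-Curtis matrices, group OTU
# overlap, within-group beta-diversity summaries and UPGMA dendrograms.

#' Per-sample alpha-diversity indices
#'
#' Computes observed richness, singleton and doubleton counts, the
#' bias-corrected Chao1 estimator
#' `S_obs + F1 (F1 - 1) / (2 (F2 + 1))`, Shannon entropy (natural log) and
#' the inverse Simpson index.  Counts must be integers because Chao1 is
#' built on singleton/doubleton frequencies; compute on a rarefied table
#' so that depths are comparable across samples.
#'
#' @param cm a [community_matrix()].
#' @return a data.frame with one row per sample and columns `sample_id`,
#'   `S_obs`, `F1`, `F2`, `chao1`, `shannon`, `invsimpson`.
#' @export
alpha_diversity <- function(cm) {
  stopifnot(inherits(cm, "community_matrix"))
  x <- cm$counts
  if (any(rowSums(x) == 0)) {
    stop("empty sample(s): ",
         paste(sample_ids(cm)[rowSums(x) == 0], collapse = ", "))
  }
  s_obs <- rowSums(x > 0)
  f1 <- rowSums(x == 1)
  f2 <- rowSums(x == 2)
  chao1 <- s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  shannon <- vegan::diversity(x, index = "shannon")
  invsimpson <- vegan::diversity(x, index = "invsimpson")
  data.frame(sample_id = sample_ids(cm), S_obs = s_obs, F1 = f1, F2 = f2,
             chao1 = chao1, shannon = as.numeric(shannon),
             invsimpson = as.numeric(invsimpson), row.names = NULL)
}

#' Rarefaction curves of Chao1 richness (or observed richness)
#'
#' For each sample and each depth, subsamples without replacement `reps`
#' times and averages the chosen statistic.  Depths exceeding a sample's
#' total are truncated to the total, with a warning.
#'
#' @param cm a [community_matrix()].
#' @param depths increasing vector of subsampling depths.
#' @param reps number of random subsamples per depth.
#' @param seed integer seed.
#' @param statistic `"chao1"` (default) or `"richness"`.
#' @return a data.frame with columns `sample_id`, `depth`, `value`.
#' @export
rarefaction_curve <- function(cm, depths, reps = 10, seed = 1,
                              statistic = c("chao1", "richness")) {
  stopifnot(inherits(cm, "community_matrix"))
  statistic <- match.arg(statistic)
  depths <- sort(unique(as.integer(depths)))
  totals <- rowSums(cm$counts)
  if (any(depths > min(totals)))
    warning("depths exceeding some sample totals were truncated")
  stat_fun <- function(v) {
    if (statistic == "richness") return(sum(v > 0))
    s <- sum(v > 0); f1 <- sum(v == 1); f2 <- sum(v == 2)
    s + f1 * (f1 - 1) / (2 * (f2 + 1))
  }
  out <- with_seed(seed, {
    res <- list()
    for (i in seq_len(nrow(cm$counts))) {
      v <- cm$counts[i, ]
      for (d in depths) {
        dd <- min(d, totals[i])
        vals <- replicate(reps, {
          sub <- suppressWarnings(vegan::rrarefy(matrix(v, nrow = 1), dd))
          stat_fun(as.vector(sub))
        })
        res[[length(res) + 1]] <- data.frame(
          sample_id = sample_ids(cm)[i], depth = dd, value = mean(vals))
      }
    }
    do.call(rbind, res)
  })
  rownames(out) <- NULL
  out
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(x, y) = sum |x - y| / sum (x + y)`, computed with
#' [vegan::vegdist()]; bounded in `[0, 1]` with zero diagonal.
#'
#' @param cm a [community_matrix()] (or plain abundance matrix).
#' @return a `dist_matrix` of kind `"dissimilarity"`.
#' @export
bray_curtis <- function(cm) {
  x <- if (inherits(cm, "community_matrix")) cm$counts else as.matrix(cm)
  if (nrow(x) < 2) stop("need at least two samples")
  if (any(rowSums(x) == 0)) stop("sample(s) with zero total reads")
  dist_matrix(vegan::vegdist(x, method = "bray"), kind = "dissimilarity",
              ids = rownames(x))
}

#' Per-group OTU occurrence overlap
#'
#' An OTU is counted as present in a group if any sample of that group has
#' a positive count.  Reports per-group OTU totals, the number shared by
#' all groups, and per-group exclusive OTU counts and percentages (of the
#' total OTU number).
#'
#' @param cm a [community_matrix()].
#' @param groups group label per sample, aligned with rows of `cm`.
#' @return a list with `per_group`, `shared_all`, `exclusive`,
#'   `exclusive_pct`, `total_otus`.
#' @export
group_overlap <- function(cm, groups) {
  stopifnot(inherits(cm, "community_matrix"))
  if (length(groups) != nrow(cm$counts))
    stop("groups must match the number of samples")
  groups <- as.character(groups)
  lv <- unique(groups)
  pres <- vapply(lv, function(g) {
    colSums(cm$counts[groups == g, , drop = FALSE] > 0) > 0
  }, logical(ncol(cm$counts)))
  n_groups_per_otu <- rowSums(pres)
  if (any(n_groups_per_otu == 0)) stop("OTU absent from all samples")
  per_group <- colSums(pres)
  excl <- vapply(lv, function(g) sum(pres[, g] & n_groups_per_otu == 1),
                 integer(1))
  list(per_group = per_group,
       shared_all = sum(n_groups_per_otu == length(lv)),
       exclusive = excl,
       exclusive_pct = 100 * excl / ncol(cm$counts),
       total_otus = ncol(cm$counts))
}

#' Within-group beta-diversity summary
#'
#' Mean and SD of the pairwise dissimilarities among samples of each group
#' (upper-triangle, within-group pairs only).  Groups with fewer than two
#' samples are reported as `NA`.
#'
#' @param d a `dist_matrix` of kind `"dissimilarity"`.
#' @param groups group label per sample.
#' @param sd_type `"sample"` (n - 1 denominator, default) or `"population"`.
#' @return data.frame with columns `group`, `n_pairs`, `mean`, `sd`.
#' @export
within_group_beta <- function(d, groups, sd_type = c("sample", "population")) {
  stopifnot(inherits(d, "dist_matrix"))
  sd_type <- match.arg(sd_type)
  m <- as.matrix(d)
  if (length(groups) != nrow(m)) stop("groups must match samples")
  lv <- unique(as.character(groups))
  out <- lapply(lv, function(g) {
    idx <- which(groups == g)
    if (length(idx) < 2)
      return(data.frame(group = g, n_pairs = 0L, mean = NA_real_,
                        sd = NA_real_))
    sub <- m[idx, idx]
    v <- sub[upper.tri(sub)]
    s <- stats::sd(v)
    if (sd_type == "population") s <- s * sqrt((length(v) - 1) / length(v))
    data.frame(group = g, n_pairs = length(v), mean = mean(v), sd = s)
  })
  do.call(rbind, out)
}

#' Hierarchical clustering of samples as a newick tree
#'
#' Average-linkage (UPGMA) agglomeration of a dissimilarity matrix by
#' default, serialized as newick with branch lengths (leaf heights are half
#' the merge dissimilarities, so two samples at distance 0.4 sit on two
#' branches of length 0.2).
#'
#' @param d a `dist_matrix` of kind `"dissimilarity"`.
#' @param linkage `"average"` (UPGMA, default), `"complete"` or `"ward.D2"`.
#' @param file optional path; when given the newick string is also written
#'   there.
#' @return the newick string (invisibly also an `ape::phylo` via attribute
#'   `phylo`).
#' @export
upgma_tree <- function(d, linkage = c("average", "complete", "ward.D2"),
                       file = NULL) {
  stopifnot(inherits(d, "dist_matrix"))
  linkage <- match.arg(linkage)
  m <- as.matrix(d)
  if (any(is.na(m))) stop("NaN distance")
  hc <- stats::hclust(stats::as.dist(m), method = linkage)
  phy <- ape::as.phylo(hc)
  nwk <- ape::write.tree(phy)
  if (!is.null(file)) writeLines(nwk, file)
  attr(nwk, "phylo") <- phy
  nwk
}
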