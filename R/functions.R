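# Taxon-to-function mapping (FAPROTAX-style): project a community table
# onto ecological functions via substring rules on taxonomy lineages, and
# compare function profiles between groups.

#' Read a function mapping from a two-column TSV
#'
#' Each row is `function <tab> rule`; a function may span several rows
#' (one rule each).  Rules are plain substrings matched case-insensitively
#' against the full semicolon-delimited lineage.  A small demonstration
#' mapping covering common freshwater functions ships with the package
#' (`system.file("extdata", "function_mapping_demo.tsv", package =
#' "aquassembly")`); it is a synthetic stand-in, not the FAPROTAX
#' database.
#'
#' @param path TSV path (no header, or a header line starting `function`).
#' @return a named list of class `function_mapping`: function name ->
#'   character vector of rules.
#' @export
read_function_mapping <- function(path) {
  tx <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8", comment.char = "#")
  if (identical(tolower(tx[1, 1]), "function")) tx <- tx[-1, , drop = FALSE]
  if (!nrow(tx)) stop("empty mapping file")
  mp <- split(as.character(tx[[2]]), as.character(tx[[1]]))
  structure(mp, class = "function_mapping")
}

#' Apply a taxon-to-function mapping to a community table
#'
#' An OTU contributes its reads to every function whose rule matches its
#' lineage (multi-assignment, no read splitting).  Relative abundances are
#' computed per sample against the total annotated reads by default, or
#' against the total sample reads with `denominator = "sample"`.
#'
#' @param cm a [community_matrix()] with taxonomy.
#' @param mapping a `function_mapping` (or named list of rule vectors).
#' @param denominator `"annotated"` (default) or `"sample"`.
#' @return an object of class `function_table`: `counts` (function x
#'   sample), `relative`, `assigned_otus`, `assigned_fraction`,
#'   `denominator`.
#' @export
apply_mapping <- function(cm, mapping,
                          denominator = c("annotated", "sample")) {
  stopifnot(inherits(cm, "community_matrix"))
  denominator <- match.arg(denominator)
  if (!length(mapping)) stop("empty mapping")
  if (is.null(cm$taxonomy)) stop("community has no taxonomy")
  tax <- cm$taxonomy[otu_ids(cm)]
  fn <- names(mapping)
  hit <- vapply(fn, function(f) {
    h <- rep(FALSE, length(tax))
    for (rule in mapping[[f]]) {
      h <- h | (!is.na(tax) & grepl(rule, tax, ignore.case = TRUE))
    }
    h
  }, logical(length(tax)))
  counts <- t(cm$counts %*% hit)          # function x sample
  rownames(counts) <- fn
  assigned <- rowSums(hit) > 0            # per OTU
  denom <- if (denominator == "annotated") {
    rowSums(cm$counts[, assigned, drop = FALSE])   # per-sample annotated reads
  } else {
    rowSums(cm$counts)
  }
  rel <- sweep(counts, 2, pmax(denom, 1), "/")  # guard zero denominators
  structure(list(counts = counts, relative = rel,
                 assigned_otus = sum(assigned),
                 assigned_fraction = mean(assigned),
                 denominator = denominator),
            class = "function_table")
}

#' @export
print.function_table <- function(x, ...) {
  cat(sprintf(
    "function_table: %d functions x %d samples; %d OTUs (%.0f%%) assigned\n",
    nrow(x$counts), ncol(x$counts), x$assigned_otus,
    100 * x$assigned_fraction))
  invisible(x)
}

#' Compare function profiles between two groups
#'
#' Runs the permutation difference-of-means test ([whites_test()]) per
#' function on the relative abundances of two groups, corrects across
#' functions by Benjamini-Hochberg, and reports which group each
#' significant function is enriched in.
#'
#' @param ft a `function_table`.
#' @param groups group label per sample (exactly two distinct labels among
#'   the selected samples).
#' @param alpha significance level on the q-values (default 0.05).
#' @param n_perm permutations per function when enumeration is infeasible.
#' @param seed integer seed.
#' @return data.frame with columns `func`, `statistic`, `p`, `q`,
#'   `enriched_in`, `significant`.
#' @export
compare_profiles <- function(ft, groups, alpha = 0.05, n_perm = 9999,
                             seed = 1) {
  stopifnot(inherits(ft, "function_table"))
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) != 2) stop("exactly two groups required")
  if (length(groups) != ncol(ft$relative))
    stop("groups must match samples")
  res <- lapply(seq_len(nrow(ft$relative)), function(i) {
    x <- ft$relative[i, groups == lv[1]]
    y <- ft$relative[i, groups == lv[2]]
    wt <- whites_test(x, y, n_perm = n_perm, seed = derive_seed(seed, i))
    data.frame(func = rownames(ft$relative)[i], statistic = wt$statistic,
               p = wt$p)
  })
  out <- do.call(rbind, res)
  out$q <- bh_adjust(out$p)
  out$enriched_in <- ifelse(out$statistic > 0, lv[1],
                            ifelse(out$statistic < 0, lv[2], NA))
  out$significant <- out$q < alpha
  out
}
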