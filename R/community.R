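#' Construct a community matrix
#'
#' The central data container: a samples-by-OTU table of non-negative
#' integer read counts, with optional per-OTU taxonomy strings
#' (semicolon-delimited lineages, as produced by SILVA-style classifiers).
#'
#' @param counts numeric matrix, samples as rows, OTUs as columns; must be
#'   non-negative integers.  Row and column names are the sample and OTU ids.
#' @param taxonomy optional named character vector mapping OTU ids to
#'   lineage strings; every name must be a column of `counts`.
#' @return an object of class `community_matrix` with elements `counts`
#'   (integer matrix) and `taxonomy`.
#' @export
community_matrix <- function(counts, taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("S", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("OTU", seq_len(ncol(counts)))
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample ids in counts")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate OTU ids in counts")
  if (any(is.na(counts))) stop("counts contain missing values")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be integers")
  storage.mode(counts) <- "integer"
  if (!is.null(taxonomy)) {
    if (is.null(names(taxonomy))) stop("taxonomy must be a named vector")
    bad <- setdiff(names(taxonomy), colnames(counts))
    if (length(bad))
      stop("taxonomy keys not present in counts: ",
           paste(utils::head(bad, 5), collapse = ", "))
    taxonomy <- taxonomy[colnames(counts)[colnames(counts) %in%
                                            names(taxonomy)]]
  }
  structure(list(counts = counts, taxonomy = taxonomy),
            class = "community_matrix")
}

#' @export
print.community_matrix <- function(x, ...) {
  cat(sprintf("community_matrix: %d samples x %d OTUs, %s reads%s\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(as.numeric(x$counts)), big.mark = ","),
              if (is.null(x$taxonomy)) "" else "; taxonomy attached"))
  invisible(x)
}

#' @export
dim.community_matrix <- function(x) dim(x$counts)

sample_ids <- function(cm) rownames(cm$counts)
otu_ids <- function(cm) colnames(cm$counts)

#' Filter low-abundance and unwanted OTUs
#'
#' Removes OTUs whose total read count across all samples falls below
#' `min_total_reads` (a standard guard against random sequencing error),
#' and OTUs whose taxonomy string contains any of `exclude_patterns`
#' (case-insensitive substring match; chloroplast sequences by default).
#' Sample order is unchanged.  The operation is idempotent.
#'
#' @param cm a [community_matrix()].
#' @param min_total_reads OTUs with total reads strictly below this are
#'   dropped (default 10, i.e. OTUs with fewer than 10 reads).
#' @param exclude_patterns character vector of taxonomy substrings to
#'   exclude; ignored for OTUs without taxonomy.
#' @return the filtered `community_matrix`.
#' @export
preprocess_community <- function(cm, min_total_reads = 10,
                                 exclude_patterns = "Chloroplast") {
  stopifnot(inherits(cm, "community_matrix"))
  totals <- colSums(cm$counts)
  keep <- totals >= min_total_reads
  if (!is.null(cm$taxonomy) && length(exclude_patterns)) {
    tax <- cm$taxonomy[otu_ids(cm)]
    hit <- rep(FALSE, ncol(cm$counts))
    for (pat in exclude_patterns) {
      hit <- hit | (!is.na(tax) &
                      grepl(pat, tax, ignore.case = TRUE, fixed = FALSE))
    }
    keep <- keep & !hit
  }
  if (!any(keep)) stop("empty community: all OTUs removed by preprocessing")
  community_matrix(cm$counts[, keep, drop = FALSE],
                   taxonomy = if (is.null(cm$taxonomy)) NULL else
                     cm$taxonomy[names(cm$taxonomy) %in%
                                   colnames(cm$counts)[keep]])
}

#' Rarefy all samples to a common sequencing depth
#'
#' Subsamples each sample to exactly `depth` reads without replacement
#' (hypergeometric), one seeded draw per table, via [vegan::rrarefy()].
#'
#' @param cm a [community_matrix()].
#' @param depth target depth; every sample total must be at least `depth`.
#'   Defaults to the smallest sample total.
#' @param seed integer seed making the draw reproducible.
#' @return a rarefied `community_matrix` whose row sums all equal `depth`.
#' @export
rarefy_community <- function(cm, depth = min(rowSums(cm$counts)), seed = 1) {
  stopifnot(inherits(cm, "community_matrix"))
  totals <- rowSums(cm$counts)
  short <- totals < depth
  if (any(short)) {
    stop("samples with fewer than ", depth, " reads: ",
         paste(sample_ids(cm)[short], collapse = ", "))
  }
  # rrarefy's "observed counts" heuristic warning misfires on valid
  # integer tables; inputs are already validated above
  rar <- with_seed(seed, suppressWarnings(vegan::rrarefy(cm$counts, depth)))
  community_matrix(rar, taxonomy = cm$taxonomy)
}

#' Default habitat-group rules for a river/lake salinity gradient
#'
#' River samples form one group; lake samples are split by salinity into
#' freshwater (< 1 permille), low-brackish (1 to < 8 permille) and
#' high-brackish (>= 8 permille) groups.  Bin edges are configurable.
#'
#' @param freshwater_max upper salinity bound (permille) for freshwater lakes.
#' @param brackish_max upper salinity bound for low-brackish lakes.
#' @return a data.frame of rules with columns `ecosystem`, `min_salinity`,
#'   `max_salinity` (half-open `[min, max)` intervals) and `group`.
#' @export
habitat_rules <- function(freshwater_max = 1, brackish_max = 8) {
  data.frame(
    ecosystem = c("river", "lake", "lake", "lake"),
    min_salinity = c(0, 0, freshwater_max, brackish_max),
    max_salinity = c(Inf, freshwater_max, brackish_max, Inf),
    group = c("Group I", "Group II", "Group III", "Group IV"),
    stringsAsFactors = FALSE
  )
}

#' Assign samples to habitat groups
#'
#' Fills the `habitat_group` column of a metadata table from ecosystem type
#' and salinity, using half-open salinity intervals per ecosystem.
#'
#' @param md metadata data.frame with columns `ecosystem` and `salinity`.
#' @param rules rule table as returned by [habitat_rules()].
#' @return `md` with a `habitat_group` column.
#' @export
assign_habitat_groups <- function(md, rules = habitat_rules()) {
  stopifnot(all(c("ecosystem", "salinity") %in% names(md)))
  if (any(is.na(md$salinity)) || any(md$salinity < 0))
    stop("salinity must be non-negative and complete")
  grp <- rep(NA_character_, nrow(md))
  for (r in seq_len(nrow(rules))) {
    ok <- md$ecosystem == rules$ecosystem[r] &
      md$salinity >= rules$min_salinity[r] &
      md$salinity < rules$max_salinity[r]
    grp[ok & is.na(grp)] <- rules$group[r]
  }
  if (any(is.na(grp))) {
    stop("samples matched no habitat rule: ",
         paste(md$sample_id[is.na(grp)] %||% which(is.na(grp)),
               collapse = ", "))
  }
  md$habitat_group <- grp
  md
}
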