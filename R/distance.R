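#' Construct a distance matrix container
#'
#' Symmetric pairwise matrix of dissimilarities, similarities or geographic
#' distances, with sample ids and a `kind` tag.  Dissimilarity and
#' geographic matrices must have a zero diagonal, similarity matrices a
#' unit diagonal.
#'
#' @param values square numeric matrix, or a [stats::dist] object.
#' @param kind one of `"dissimilarity"`, `"similarity"`, `"geographic"`.
#' @param ids optional sample ids (defaults to dimnames).
#' @return an object of class `dist_matrix`.
#' @export
dist_matrix <- function(values,
                        kind = c("dissimilarity", "similarity", "geographic"),
                        ids = NULL) {
  kind <- match.arg(kind)
  if (inherits(values, "dist")) values <- as.matrix(values)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("distance matrix must be square")
  if (any(is.na(values))) stop("distance matrix contains NA")
  if (max(abs(values - t(values))) > 1e-8)
    stop("distance matrix must be symmetric")
  ids <- ids %||% rownames(values) %||% paste0("S", seq_len(nrow(values)))
  dimnames(values) <- list(ids, ids)
  want_diag <- if (kind == "similarity") 1 else 0
  if (max(abs(diag(values) - want_diag)) > 1e-8)
    stop("diagonal must be ", want_diag, " for kind '", kind, "'")
  structure(list(ids = ids, values = values, kind = kind),
            class = "dist_matrix")
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("dist_matrix (%s): %d samples\n", x$kind, length(x$ids)))
  invisible(x)
}

#' @export
as.matrix.dist_matrix <- function(x, ...) x$values

# Strict upper-triangle entries as a vector (pairs in column-major order).
dm_upper <- function(x) {
  m <- as.matrix(x)
  m[upper.tri(m)]
}

#' Convert between dissimilarity and similarity views
#'
#' For Bray-Curtis-type matrices bounded in `[0, 1]`,
#' similarity = 1 - dissimilarity.
#'
#' @param x a `dist_matrix`.
#' @return the complementary `dist_matrix`.
#' @export
dm_complement <- function(x) {
  stopifnot(inherits(x, "dist_matrix"), x$kind != "geographic")
  kind <- if (x$kind == "dissimilarity") "similarity" else "dissimilarity"
  dist_matrix(1 - as.matrix(x), kind = kind, ids = x$ids)
}

#' Write a distance matrix as square TSV
#' @param x a `dist_matrix`.
#' @param path output path.
#' @return `x`, invisibly.
#' @export
write_dist_matrix <- function(x, path) {
  df <- data.frame(sample_id = x$ids, as.matrix(x), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(x)
}
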