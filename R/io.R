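# Text I/O: tab-delimited count tables, two-column taxonomy files and
# per-sample metadata CSV.  All files are UTF-8.

#' Read a community table (and optional taxonomy) from TSV
#'
#' The count table is tab-delimited with ids in the first row and column.
#' By default rows are samples and columns OTUs; set `otus_as_rows = TRUE`
#' for the transposed layout, or leave `otus_as_rows = NULL` to auto-detect
#' (row labels matching `^OTU` are taken to be OTUs).
#'
#' @param counts_path path to the count TSV.
#' @param taxonomy_path optional path to a two-column TSV
#'   (otu_id, semicolon-delimited lineage), no header required.
#' @param otus_as_rows logical or NULL (auto-detect).
#' @return a [community_matrix()].
#' @export
read_community <- function(counts_path, taxonomy_path = NULL,
                           otus_as_rows = NULL) {
  if (!file.exists(counts_path)) stop("no such file: ", counts_path)
  tab <- utils::read.delim(counts_path, row.names = 1, check.names = FALSE,
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  m <- as.matrix(tab)
  if (!is.numeric(m)) {
    bad <- which(!vapply(tab, is.numeric, TRUE))[1]
    stop("non-numeric counts in column '", names(tab)[bad],
         "' of ", counts_path)
  }
  if (any(abs(m - round(m)) > 1e-8)) {
    idx <- which(abs(m - round(m)) > 1e-8, arr.ind = TRUE)[1, ]
    stop("non-integer count at row '", rownames(m)[idx[1]],
         "', column '", colnames(m)[idx[2]], "' of ", counts_path)
  }
  if (is.null(otus_as_rows)) {
    otus_as_rows <- mean(grepl("^OTU", rownames(m), ignore.case = TRUE)) >
      mean(grepl("^OTU", colnames(m), ignore.case = TRUE))
  }
  if (otus_as_rows) m <- t(m)
  taxonomy <- NULL
  if (!is.null(taxonomy_path)) {
    tx <- utils::read.delim(taxonomy_path, header = FALSE,
                            stringsAsFactors = FALSE,
                            fileEncoding = "UTF-8")
    if (identical(tolower(tx[1, 1]), "otu_id")) tx <- tx[-1, , drop = FALSE]
    taxonomy <- stats::setNames(as.character(tx[[2]]), as.character(tx[[1]]))
  }
  community_matrix(m, taxonomy = taxonomy)
}

#' Write a community table (and taxonomy) to TSV
#'
#' @param cm a [community_matrix()].
#' @param counts_path output path for the count TSV (samples as rows).
#' @param taxonomy_path optional output path for the two-column taxonomy TSV.
#' @return `cm`, invisibly.
#' @export
write_community <- function(cm, counts_path, taxonomy_path = NULL) {
  stopifnot(inherits(cm, "community_matrix"))
  df <- data.frame(sample_id = sample_ids(cm), cm$counts,
                   check.names = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  if (!is.null(taxonomy_path) && !is.null(cm$taxonomy)) {
    utils::write.table(
      data.frame(otu_id = names(cm$taxonomy), lineage = unname(cm$taxonomy)),
      taxonomy_path, sep = "\t", quote = FALSE, row.names = FALSE,
      col.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(cm)
}

#' Read per-sample metadata from CSV
#'
#' Requires columns `sample_id`, `ecosystem`, `latitude`, `longitude` and
#' `salinity`; any further columns are treated as environmental variables.
#'
#' @param path CSV path with a header row.
#' @return a data.frame, one row per sample.
#' @export
read_metadata <- function(path) {
  md <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  req <- c("sample_id", "ecosystem", "latitude", "longitude", "salinity")
  miss <- setdiff(req, names(md))
  if (length(miss)) stop("metadata lacks columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(md$sample_id)) stop("duplicate sample ids in metadata")
  if (any(md$latitude < -90 | md$latitude > 90)) stop("latitude out of range")
  if (any(md$longitude < -180 | md$longitude > 180))
    stop("longitude out of range")
  if (any(md$salinity < 0)) stop("salinity must be non-negative")
  md
}
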