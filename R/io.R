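#' Read a count table from TSV
#'
#' Reads the package's plain-text count-table dialect: a tab-separated file
#' whose first column `taxon_id` holds taxon identifiers and whose
#' remaining columns hold one sample each, with non-negative integer cells.
#' Malformed cells are rejected with their row and column coordinates.
#'
#' @param path file path.
#' @return sample x taxon count matrix (samples as rows, as used throughout
#'   the package).
#' @seealso [write_count_table()] for the inverse; the two round-trip
#'   losslessly.
#' @export
read_count_table <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2 || names(df)[1] != "taxon_id")
    stop("malformed count table ", path, ": first column must be 'taxon_id'")
  taxa <- as.character(df[[1]])
  if (anyDuplicated(taxa)) stop("duplicate taxon_id in ", path)
  for (j in 2:ncol(df)) {
    col <- df[[j]]
    if (!is.numeric(col))
      stop(sprintf("%s: column '%s' is not numeric", path, names(df)[j]))
    bad <- which(is.na(col) | col < 0 | col != floor(col))
    if (length(bad))
      stop(sprintf("%s: invalid count at row %d, column '%s' (value %s)",
                   path, bad[1], names(df)[j], as.character(col[bad[1]])))
  }
  mat <- t(as.matrix(df[, -1, drop = FALSE]))
  colnames(mat) <- taxa
  storage.mode(mat) <- "double"
  mat
}

#' Write a count table to TSV
#'
#' @param mat sample x taxon count matrix.
#' @param path file path.
#' @param drop_empty_taxa omit taxa with zero total (default `FALSE`).
#' @return `path`, invisibly.
#' @export
write_count_table <- function(mat, path, drop_empty_taxa = FALSE) {
  mat <- as_count_matrix(mat, require_positive_rows = FALSE)
  if (drop_empty_taxa) mat <- mat[, colSums(mat) > 0, drop = FALSE]
  df <- data.frame(taxon_id = colnames(mat), t(mat),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write count tables in BIOM format
#'
#' Interoperability layer over the Bioconductor *biomformat* package
#' (JSON BIOM); taxon and sample identifiers and integer counts are
#' preserved round-trip.  Requires the suggested *biomformat* package.
#'
#' @param path file path.
#' @return `read_biom_table()`: a sample x taxon count matrix.
#' @export
read_biom_table <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE))
    stop("the 'biomformat' package is required for BIOM input")
  b <- biomformat::read_biom(path)
  mat <- t(as.matrix(biomformat::biom_data(b)))
  as_count_matrix(mat, require_positive_rows = FALSE)
}

#' @param mat sample x taxon count matrix.
#' @rdname read_biom_table
#' @export
write_biom_table <- function(mat, path) {
  if (!requireNamespace("biomformat", quietly = TRUE))
    stop("the 'biomformat' package is required for BIOM output")
  mat <- as_count_matrix(mat, require_positive_rows = FALSE)
  biomformat::write_biom(biomformat::make_biom(t(mat)), path)
  invisible(path)
}
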