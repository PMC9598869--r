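#' Construct a community
#'
#' A community is a named numeric vector mapping taxon identifiers to
#' non-negative integer abundances (numbers of individuals).  Totals at
#' environmental scale (10^8) exceed the integer range in sums, so counts
#' are stored as doubles but must be whole numbers.
#'
#' @param abundances numeric vector of non-negative whole numbers.
#' @param taxon_ids character vector of unique taxon identifiers; defaults
#'   to `names(abundances)`.
#' @return a named numeric vector of class `"community"`.
#' @export
#' @examples
#' community(c(a = 3, b = 2, c = 1))
community <- function(abundances, taxon_ids = names(abundances)) {
  if (is.null(taxon_ids))
    stop("taxon_ids are required (supply names or the taxon_ids argument)")
  x <- structure(setNames(as.double(abundances), as.character(taxon_ids)),
                 class = "community")
  validate_community(x)
  x
}

validate_community <- function(x) {
  if (is.null(names(x)) || anyNA(names(x)))
    stop("community must have taxon ids as names")
  if (anyDuplicated(names(x)))
    stop("duplicate taxon ids in community")
  if (anyNA(x) || any(x < 0))
    stop("community abundances must be non-negative")
  if (any(x != floor(x)))
    stop("community abundances must be whole numbers")
  invisible(x)
}

#' @export
print.community <- function(x, ...) {
  cat(sprintf("<community> %d taxa (%d present), %s individuals\n",
              length(x), sum(x > 0), format(sum(x), big.mark = ",")))
  invisible(x)
}

#' Total individuals and richness of a community
#'
#' @param x a [community()] or named numeric vector of counts.
#' @return `community_size()`: the total number of individuals;
#'   `community_richness()`: the number of taxa with positive abundance.
#' @export
community_size <- function(x) sum(unclass(x))

#' @rdname community_size
#' @export
community_richness <- function(x) sum(unclass(x) > 0)

# Coerce and validate count-matrix input (samples x taxa, doubles).
as_count_matrix <- function(mat, require_positive_rows = TRUE) {
  mat <- as.matrix(mat)
  storage.mode(mat) <- "double"
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("s%02d", seq_len(nrow(mat)))
  if (is.null(colnames(mat))) colnames(mat) <- sprintf("t%05d", seq_len(ncol(mat)))
  if (anyDuplicated(rownames(mat))) stop("duplicate sample ids")
  if (anyDuplicated(colnames(mat))) stop("duplicate taxon ids")
  if (anyNA(mat) || any(mat < 0)) stop("counts must be non-negative")
  if (any(mat != floor(mat))) stop("counts must be whole numbers")
  if (require_positive_rows && any(rowSums(mat) == 0))
    stop("every sample must have a positive total; empty samples: ",
         paste(rownames(mat)[rowSums(mat) == 0], collapse = ", "))
  mat
}

#' Restrict a count matrix to a set of taxa
#'
#' Subsets the columns of a sample x taxon count matrix without any
#' renormalization, e.g. to analyse the abundant or rare subcommunity.
#'
#' @param mat sample x taxon count matrix.
#' @param taxa character vector of taxon ids to keep.
#' @param drop_empty_taxa drop taxa whose column total is zero after
#'   subsetting (default `TRUE`); the regional pool of a subcommunity is
#'   defined on its present taxa only.
#' @return the restricted count matrix (samples unchanged).
#' @export
subset_taxa <- function(mat, taxa, drop_empty_taxa = TRUE) {
  mat <- as_count_matrix(mat, require_positive_rows = FALSE)
  missing <- setdiff(taxa, colnames(mat))
  if (length(missing))
    stop("taxa not in matrix: ", paste(utils::head(missing, 3), collapse = ", "))
  sub <- mat[, colnames(mat) %in% taxa, drop = FALSE]
  if (drop_empty_taxa) sub <- sub[, colSums(sub) > 0, drop = FALSE]
  sub
}
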