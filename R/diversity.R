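#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' `1 - 2 * sum(pmin(x, y)) / (sum(x) + sum(y))`: 0 for identical
#' composition, 1 for disjoint taxon support.  Vectors must be aligned on
#' the same taxa (names, when present, must match in order).
#'
#' @param x,y non-negative abundance vectors of equal length; at least one
#'   must have a positive total.
#' @return dissimilarity in `[0, 1]`.
#' @export
#' @examples
#' bray_curtis(c(3, 1, 0), c(1, 1, 2)) # 0.5
bray_curtis <- function(x, y) {
  x <- as.double(unclass(x)); y <- as.double(unclass(y))
  if (length(x) != length(y))
    stop("x and y must be aligned on the same taxa")
  if (!is.null(names(x)) && !is.null(names(y)) && !all(names(x) == names(y)))
    stop("x and y must be aligned on the same taxa (names differ)")
  if (any(x < 0) || any(y < 0)) stop("abundances must be non-negative")
  denom <- sum(x) + sum(y)
  if (denom == 0) stop("Bray-Curtis undefined: both vectors are all-zero")
  1 - 2 * sum(pmin(x, y)) / denom
}

# ordered sample pairs matching the layout of stats::dist / vegan::vegdist
pair_grid <- function(ids) {
  n <- length(ids)
  first <- rep(seq_len(n - 1), times = (n - 1):1)
  second <- unlist(lapply(seq_len(n - 1), function(a) seq.int(a + 1, n)),
                   use.names = FALSE)
  data.frame(sample_i = ids[first], sample_j = ids[second],
             stringsAsFactors = FALSE)
}

# all pairwise Bray-Curtis values of a samples x taxa matrix (vegan backend)
pairwise_bc <- function(mat) as.numeric(vegan::vegdist(mat, method = "bray"))

#' All pairwise Bray-Curtis dissimilarities of a count matrix
#'
#' Computes the `n(n-1)/2` pairwise Bray-Curtis values of a sample x taxon
#' matrix, optionally restricted to a taxon subset (columns are subset
#' without renormalization, so subcommunity dissimilarities retain the raw
#' count structure).  Samples whose total is zero within the subset cannot
#' enter a Bray-Curtis comparison; their pairs are excluded with a warning.
#'
#' @param mat sample x taxon count matrix.
#' @param subset optional character vector of taxon ids.
#' @return list with `pairs` (data frame: `sample_i`, `sample_j`,
#'   `bray_curtis`) and `mean` (arithmetic mean over retained pairs).
#' @export
pairwise_beta <- function(mat, subset = NULL) {
  mat <- as_count_matrix(mat, require_positive_rows = FALSE)
  if (!is.null(subset)) mat <- subset_taxa(mat, subset, drop_empty_taxa = FALSE)
  empty <- rowSums(mat) == 0
  if (any(empty)) {
    warning("excluding pair(s) involving zero-total sample(s): ",
            paste(rownames(mat)[empty], collapse = ", "))
    mat <- mat[!empty, , drop = FALSE]
  }
  if (nrow(mat) < 2) stop("need at least 2 non-empty samples")
  pairs <- pair_grid(rownames(mat))
  pairs$bray_curtis <- pairwise_bc(mat)
  list(pairs = pairs, mean = mean(pairs$bray_curtis))
}

#' Partition taxa into abundant and rare subcommunities
#'
#' Ranks taxa by their total count over all samples (descending; ties
#' broken by taxon id, ascending) and takes the shortest prefix whose
#' cumulative share of the grand total reaches `threshold` as the abundant
#' subcommunity; the remaining taxa with positive totals form the rare
#' subcommunity.  With the default threshold, the top-ranked taxa holding
#' 80% of the total relative abundance are "abundant" and typically occupy
#' well under 20% of the richness under a lognormal SAD.
#'
#' @param mat sample x taxon count matrix with a positive grand total.
#' @param threshold cumulative relative-abundance cutoff in (0, 1).
#' @return list of class `"subcommunity_partition"` with character vectors
#'   `abundant` and `rare` plus the `threshold` used.  Taxa with zero total
#'   belong to neither set.
#' @export
#' @examples
#' m <- rbind(s1 = c(t1 = 50, t2 = 30, t3 = 15, t4 = 5))
#' partition_abundant_rare(m)$abundant
partition_abundant_rare <- function(mat, threshold = 0.80) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold >= 1)
    stop("threshold must be a single number in (0, 1)")
  mat <- as_count_matrix(mat, require_positive_rows = FALSE)
  totals <- colSums(mat)
  if (sum(totals) == 0) stop("matrix has zero grand total")
  present <- totals > 0
  ord <- order(-totals[present], colnames(mat)[present])
  ids <- colnames(mat)[present][ord]
  cum <- cumsum(totals[present][ord]) / sum(totals)
  n_abundant <- which(cum >= threshold)[1]
  structure(list(abundant = ids[seq_len(n_abundant)],
                 rare = if (n_abundant < length(ids)) ids[-seq_len(n_abundant)]
                        else character(0),
                 threshold = threshold),
            class = "subcommunity_partition")
}

#' @export
print.subcommunity_partition <- function(x, ...) {
  n <- length(x$abundant) + length(x$rare)
  cat(sprintf(
    "subcommunity partition at %.0f%%: %d abundant (%.1f%% of richness), %d rare\n",
    100 * x$threshold, length(x$abundant), 100 * length(x$abundant) / n,
    length(x$rare)))
  invisible(x)
}
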