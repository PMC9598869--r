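#' Rarefy a community to a fixed depth without replacement
#'
#' Draws `depth` individuals from the community without replacement (one
#' multivariate hypergeometric draw), emulating the sequencing of a finite
#' pool of organisms.  The draw is realised by the exact conditional method,
#' taxon by taxon with [stats::rhyper()], which avoids materialising the
#' 10^8-element individual pool.  Taxa that receive no individuals are kept
#' with count 0 so seed and mock communities share a taxon universe.
#'
#' @param x a [community()].
#' @param depth number of individuals (sequences) to draw; must not exceed
#'   the community total.
#' @param rng_seed optional integer seed.
#' @return a [community()] over the same taxa with total exactly `depth`.
#' @export
#' @examples
#' comm <- community(c(a = 9000, b = 900, c = 100))
#' sub <- subsample(comm, 100, rng_seed = 1)
#' community_size(sub)
subsample <- function(x, depth, rng_seed = NULL) {
  validate_community(x)
  total <- sum(unclass(x))
  stopifnot(depth == floor(depth), depth >= 0)
  if (depth > total)
    stop("depth (", depth, ") exceeds community total (", total, ")")
  counts <- unclass(x)
  out <- numeric(length(counts))
  pos <- which(counts > 0)
  with_seed(rng_seed, {
    remaining_pool <- sum(counts[pos])
    remaining_draw <- depth
    for (i in pos) {
      if (remaining_draw == 0) break
      remaining_pool <- remaining_pool - counts[i]
      # all remaining individuals needed: forced exhaustive draw
      drawn <- if (remaining_pool == 0) remaining_draw
               else rhyper(1, counts[i], remaining_pool, remaining_draw)
      out[i] <- drawn
      remaining_draw <- remaining_draw - drawn
    }
  })
  community(out, names(counts))
}

#' Rarefy every sample of a count matrix to a common depth
#'
#' Applies [subsample()] row-wise with independent RNG substreams derived
#' from `rng_seed`, producing a mock metacommunity in which every sample has
#' exactly `depth` individuals.
#'
#' @param mat sample x taxon count matrix; every row total must be >= `depth`.
#' @param depth sequencing depth per sample.
#' @param rng_seed optional integer master seed.
#' @return a count matrix with identical dimnames and all row sums `depth`.
#' @export
subsample_matrix <- function(mat, depth, rng_seed = NULL) {
  mat <- as_count_matrix(mat)
  short <- rowSums(mat) < depth
  if (any(short))
    stop("depth ", depth, " exceeds the total of sample(s): ",
         paste(rownames(mat)[short], collapse = ", "))
  out <- mat
  for (i in seq_len(nrow(mat))) {
    seed_i <- if (is.null(rng_seed)) NULL else derive_seed(rng_seed, "subsample", depth, i)
    out[i, ] <- unclass(subsample(community(mat[i, ]), depth, rng_seed = seed_i))
  }
  out
}

#' Taxon capture statistics of a rarefied community
#'
#' Counts how many of the seed community's taxa were observed in, or lost
#' from, a rarefied (mock) community over the same taxon universe.
#'
#' @param seed the full-scale [community()].
#' @param mock the rarefied [community()], e.g. from [subsample()].
#' @return list with `observed_taxa` (mock abundance > 0) and `lost_taxa`
#'   (present in seed, absent from mock); the two always sum to the seed
#'   richness.
#' @export
capture_stats <- function(seed, mock) {
  validate_community(seed)
  validate_community(mock)
  if (length(seed) != length(mock) || !all(names(seed) == names(mock)))
    stop("seed and mock must share the same taxon universe")
  list(observed_taxa = sum(unclass(mock) > 0),
       lost_taxa = sum(unclass(seed) > 0 & unclass(mock) == 0))
}
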