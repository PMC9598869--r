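#' Regional species pool of a metacommunity
#'
#' The regional pool is the set of taxa observed anywhere in the matrix
#' (i.e. among all samples at a given sequencing depth), each carrying its
#' occurrence frequency (number of samples in which it is present) and its
#' pooled relative abundance.  Both null-model randomizers condition on this
#' pool, which must therefore be rebuilt for every depth.
#'
#' @param mat sample x taxon count matrix.
#' @return list of class `"regional_pool"`: `taxon_ids`, `frequency`,
#'   `relative_abundance`, `n_samples`.
#' @export
build_regional_pool <- function(mat) {
  mat <- as_count_matrix(mat)
  totals <- colSums(mat)
  present <- totals > 0
  structure(list(taxon_ids = colnames(mat)[present],
                 frequency = unname(colSums(mat[, present, drop = FALSE] > 0)),
                 relative_abundance = unname(totals[present] / sum(totals)),
                 n_samples = nrow(mat)),
            class = "regional_pool")
}

#' @export
print.regional_pool <- function(x, ...) {
  cat(sprintf("regional pool: %d taxa over %d samples\n",
              length(x$taxon_ids), x$n_samples))
  invisible(x)
}

# Weighted sampling of k taxa without replacement (occupancy draw).
# Exponential-key (Efraimidis-Spirakis) scheme: distributionally identical
# to successive draws with probability proportional to the remaining
# weights, but O(n log n) instead of O(n k).
sample_occupancy <- function(weights, k) {
  if (k > length(weights)) stop("richness exceeds regional pool size")
  order(rexp(length(weights)) / weights)[seq_len(k)]
}

# Shared skeleton of both randomizers.  `fill(values, ra_occupied)` returns
# the null abundances for the occupied taxa of one sample.
randomize_matrix <- function(mat, pool, fill) {
  mat <- as_count_matrix(mat)
  if (is.null(pool)) pool <- build_regional_pool(mat)
  if (!inherits(pool, "regional_pool")) stop("pool must be a regional_pool")
  pool_cols <- match(pool$taxon_ids, colnames(mat))
  if (anyNA(pool_cols)) stop("pool taxa missing from matrix")
  out <- matrix(0, nrow(mat), ncol(mat), dimnames = dimnames(mat))
  for (i in seq_len(nrow(mat))) {
    values <- mat[i, mat[i, ] > 0]
    idx <- sample_occupancy(pool$frequency, length(values))
    out[i, pool_cols[idx]] <- fill(values, pool$relative_abundance[idx])
  }
  out
}

#' Null randomization: shuffle observed abundances over random occupancy
#'
#' For each sample independently: the occupied taxa are redrawn from the
#' regional pool by weighted sampling without replacement (weights = the
#' taxa's occurrence frequencies, so widespread taxa are occupied more
#' often), holding the sample's richness fixed; the sample's observed
#' multiset of positive abundances is then assigned to the chosen taxa in
#' uniform random order.  Richness, totals and the abundance multiset of
#' every sample are conserved exactly.  Because large abundance values land
#' on different taxa in every draw, this scheme produces highly
#' *dissimilar* null communities.
#'
#' @param mat sample x taxon count matrix.
#' @param pool a [build_regional_pool()] result; defaults to the pool of
#'   `mat` itself.
#' @param rng_seed optional integer seed.
#' @return a null count matrix with the dimnames of `mat`.
#' @export
randomize_shuffle <- function(mat, pool = NULL, rng_seed = NULL) {
  with_seed(rng_seed,
    randomize_matrix(mat, pool,
                     fill = function(values, ra) values[sample.int(length(values))]))
}

#' Null randomization: fill occupancy proportionally to the regional pool
#'
#' Occupancy is redrawn exactly as in [randomize_shuffle()] (frequency
#' weighted, richness fixed).  The sample's total is then allocated over the
#' occupied taxa by first placing one individual in each (guaranteeing the
#' fixed richness) and distributing the remainder with a single multinomial
#' draw with probabilities proportional to the occupied taxa's regional
#' relative abundances.  Because every null sample is filled from the same
#' regional abundance profile, this scheme produces *similar* null
#' communities.
#'
#' @inheritParams randomize_shuffle
#' @return a null count matrix with the dimnames of `mat`.
#' @export
randomize_proportional <- function(mat, pool = NULL, rng_seed = NULL) {
  with_seed(rng_seed,
    randomize_matrix(mat, pool,
                     fill = function(values, ra) {
                       total <- sum(values)
                       k <- length(values)
                       if (total < k)
                         stop("sample total below richness: cannot seed 1 individual per occupied taxon")
                       1 + as.double(rmultinom(1, size = total - k, prob = ra))
                     }))
}

#' Ensemble of null communities for one observed matrix
#'
#' Repeats the chosen randomizer `iterations` times with independent RNG
#' substreams and records, for every iteration, the pairwise Bray-Curtis
#' dissimilarities of the null matrix.  Only these dissimilarities (an
#' `iterations x n_pairs` matrix) are retained by default, which bounds
#' memory regardless of community size; set `keep_matrices = TRUE` to also
#' keep the raw null matrices for debugging.
#'
#' @param mat sample x taxon count matrix the nulls are conditioned on.
#' @param method `"shuffle"` or `"proportional"`.
#' @param iterations number of null communities (>= 1; 1000 in the standard
#'   protocol, 100 in the fast profile).
#' @param rng_seed optional integer master seed.
#' @param keep_matrices keep the null matrices themselves (default `FALSE`).
#' @return list of class `"null_ensemble"`: `method`, `iterations`,
#'   `sample_ids`, `pairs` (as `pair_grid()`), `null_bc`
#'   (`iterations x n_pairs`), `fingerprint` of the observed matrix, and
#'   optionally `matrices`.
#' @export
#' @examples
#' m <- rbind(s1 = c(t1 = 5, t2 = 3, t3 = 0), s2 = c(t1 = 1, t2 = 0, t3 = 7))
#' ens <- generate_ensemble(m, "shuffle", iterations = 10, rng_seed = 1)
#' dim(ens$null_bc)
generate_ensemble <- function(mat, method = c("shuffle", "proportional"),
                              iterations = 1000, rng_seed = NULL,
                              keep_matrices = FALSE) {
  method <- match.arg(method)
  mat <- as_count_matrix(mat)
  stopifnot(iterations >= 1, iterations == floor(iterations))
  pool <- build_regional_pool(mat)
  randomizer <- switch(method, shuffle = randomize_shuffle,
                       proportional = randomize_proportional)
  n_pairs <- nrow(mat) * (nrow(mat) - 1) / 2
  null_bc <- matrix(NA_real_, nrow = iterations, ncol = n_pairs)
  matrices <- if (keep_matrices) vector("list", iterations)
  for (it in seq_len(iterations)) {
    seed_it <- if (is.null(rng_seed)) NULL else derive_seed(rng_seed, method, it)
    nm <- randomizer(mat, pool, rng_seed = seed_it)
    null_bc[it, ] <- pairwise_bc(nm)
    if (keep_matrices) matrices[[it]] <- nm
  }
  structure(list(method = method, iterations = iterations,
                 sample_ids = rownames(mat), pairs = pair_grid(rownames(mat)),
                 null_bc = null_bc, fingerprint = matrix_fingerprint(mat),
                 matrices = matrices),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("null ensemble: %s method, %d iterations, %d samples, mean null BC %.3f\n",
              x$method, x$iterations, length(x$sample_ids), mean(x$null_bc)))
  invisible(x)
}

# cheap fingerprint tying an ensemble to the matrix it was generated from
matrix_fingerprint <- function(mat) {
  c(nrow(mat), ncol(mat), sum(mat), sum(rowSums(mat)^2) %% 2^48,
    sum(colSums(mat > 0)^2) %% 2^48)
}
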