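#' Stochastic ratio of one sample pair
#'
#' Given the observed similarity `C` of a pair of communities and the mean
#' similarity `E_bar` of their null counterparts, the stochastic ratio is
#'
#' * `E_bar / C` when `E_bar < C` (determinism drives the pair to be more
#'   similar than expected), and
#' * `(1 - E_bar) / (1 - C)` when `E_bar >= C` (determinism drives the pair
#'   to be more dissimilar than expected).
#'
#' Both branches are ratios of the smaller to the larger quantity, so the
#' result always lies in `[0, 1]`; 1 means the observed pair is
#' indistinguishable from its null expectation (fully stochastic).  The
#' degenerate case `C = E_bar = 1` (identical pair, identical nulls) is
#' defined as 1 by the limit of the second branch.
#'
#' @param C observed similarity (1 - observed Bray-Curtis), in `[0, 1]`.
#' @param E_bar mean null similarity, in `[0, 1]`.  Both arguments are
#'   vectorized.
#' @return stochastic ratio(s) in `[0, 1]`.
#' @export
#' @examples
#' stochastic_ratio_pair(0.8, 0.4) # 0.5
#' stochastic_ratio_pair(0.2, 0.6) # 0.5
stochastic_ratio_pair <- function(C, E_bar) {
  if (any(C < 0 | C > 1 | E_bar < 0 | E_bar > 1, na.rm = TRUE))
    stop("C and E_bar must lie in [0, 1]")
  st <- ifelse(E_bar < C, E_bar / C, (1 - E_bar) / (1 - C))
  st[E_bar >= C & C == 1] <- 1 # C = E_bar = 1: identical to null
  st
}

# observed pairwise BC of `mat` aligned against an ensemble, with
# provenance check; shared by stochastic_ratio() / rc_bray() / pair_stats()
aligned_observed_bc <- function(mat, ensemble, subset) {
  if (!inherits(ensemble, "null_ensemble")) stop("ensemble must be a null_ensemble")
  mat <- as_count_matrix(mat)
  if (!is.null(subset)) mat <- subset_taxa(mat, subset, drop_empty_taxa = TRUE)
  if (!isTRUE(all.equal(matrix_fingerprint(mat), ensemble$fingerprint)))
    stop("ensemble was not generated from this matrix",
         if (!is.null(subset)) " (generate it on the subsetted matrix)")
  list(mat = mat, obs_bc = pairwise_bc(mat))
}

#' Stochastic ratio of a metacommunity against a null ensemble
#'
#' For every sample pair, the null expectation `E_bar` is the arithmetic
#' mean of the null similarities (1 - null Bray-Curtis) over all ensemble
#' iterations; the per-pair stochastic ratio follows
#' [stochastic_ratio_pair()], and the summary is the unweighted mean over
#' pairs.
#'
#' For subcommunity analyses pass the subset of taxa *and* an ensemble
#' generated on the correspondingly subsetted matrix
#' (`generate_ensemble(subset_taxa(mat, taxa), ...)`): the null models then
#' hold the subcommunity's own richness, totals and regional pool fixed,
#' mirroring how null-model tools are run on an abundant- or rare-only
#' count table.
#'
#' @param mat observed sample x taxon count matrix.
#' @param ensemble a [generate_ensemble()] result for `mat` (or for
#'   `subset_taxa(mat, subset)` when `subset` is given).
#' @param subset optional character vector of taxon ids.
#' @return list with `pairs` (data frame: `sample_i`, `sample_j`, `C`,
#'   `E_bar`, `ST`) and `mean_st`.
#' @export
stochastic_ratio <- function(mat, ensemble, subset = NULL) {
  al <- aligned_observed_bc(mat, ensemble, subset)
  C <- 1 - al$obs_bc
  E_bar <- colMeans(1 - ensemble$null_bc)
  pairs <- ensemble$pairs
  pairs$C <- C
  pairs$E_bar <- E_bar
  pairs$ST <- stochastic_ratio_pair(C, E_bar)
  list(pairs = pairs, mean_st = mean(pairs$ST))
}

#' Abundance-based Raup-Crick value of one sample pair
#'
#' Locates the observed Bray-Curtis dissimilarity within its null
#' distribution and rescales the rank to `[-1, 1]`:
#' `RC = 2 * ((n_less + 0.5 * n_equal) / n_nulls - 0.5)`.
#' Ties are detected with an absolute tolerance of 1e-12 to absorb
#' floating-point noise and weighted one half, the convention of the
#' abundance-based Raup-Crick procedure.  `RC = 1` means every null draw is
#' less dissimilar than observed (more turnover than expected), `RC = -1`
#' the opposite.
#'
#' @param observed_bc observed Bray-Curtis dissimilarity.
#' @param null_bcs numeric vector of null Bray-Curtis values (non-empty).
#' @return Raup-Crick value in `[-1, 1]`.
#' @export
#' @examples
#' rc_bray_pair(0.5, c(0.2, 0.4, 0.6, 0.8)) # 0
rc_bray_pair <- function(observed_bc, null_bcs) {
  if (!length(null_bcs)) stop("null distribution is empty")
  tol <- 1e-12
  n_equal <- sum(abs(null_bcs - observed_bc) <= tol)
  n_less <- sum(null_bcs < observed_bc - tol)
  2 * ((n_less + 0.5 * n_equal) / length(null_bcs) - 0.5)
}

#' Raup-Crick values of a metacommunity against a null ensemble
#'
#' Applies [rc_bray_pair()] to every sample pair, using the per-iteration
#' null Bray-Curtis values stored in the ensemble.  See
#' [stochastic_ratio()] for the subcommunity convention; both metrics are
#' computed from the same ensembles.
#'
#' @inheritParams stochastic_ratio
#' @return list with `pairs` (data frame: `sample_i`, `sample_j`,
#'   `observed_bc`, `RC`) and `classification` (see [classify_rc()]).
#' @export
rc_bray <- function(mat, ensemble, subset = NULL) {
  al <- aligned_observed_bc(mat, ensemble, subset)
  pairs <- ensemble$pairs
  pairs$observed_bc <- al$obs_bc
  pairs$RC <- vapply(seq_along(al$obs_bc),
                     function(p) rc_bray_pair(al$obs_bc[p], ensemble$null_bc[, p]),
                     numeric(1))
  list(pairs = pairs, classification = classify_rc(pairs$RC))
}

#' Classify Raup-Crick values into assembly-process fractions
#'
#' `RC > 0.95`: deterministically more turnover than the null expectation;
#' `RC < -0.95`: deterministically less turnover; `|RC| <= 0.95`
#' (boundary inclusive): turnover comparable to the nulls, read as
#' stochastic assembly.  The three fractions sum to 1.
#'
#' @param rc_values numeric vector of Raup-Crick values in `[-1, 1]`
#'   (non-empty).
#' @return list with `frac_above`, `frac_below`, `frac_stochastic`.
#' @export
#' @examples
#' classify_rc(c(1, -1, 0))
classify_rc <- function(rc_values) {
  if (!length(rc_values)) stop("no Raup-Crick values to classify")
  if (any(rc_values < -1 | rc_values > 1)) stop("RC values must lie in [-1, 1]")
  n <- length(rc_values)
  list(frac_above = sum(rc_values > 0.95) / n,
       frac_below = sum(rc_values < -0.95) / n,
       frac_stochastic = sum(abs(rc_values) <= 0.95) / n)
}

#' Per-pair observed/null statistics
#'
#' Joint per-pair table of all quantities entering the two stochasticity
#' metrics: observed similarity `C` and dissimilarity `D`, mean null
#' similarity `E_bar` and dissimilarity `G_bar`, the stochastic ratio `ST`
#' and the Raup-Crick value `RC`.
#'
#' @inheritParams stochastic_ratio
#' @return data frame with one row per sample pair.
#' @export
pair_stats <- function(mat, ensemble, subset = NULL) {
  st <- stochastic_ratio(mat, ensemble, subset)
  rc <- rc_bray(mat, ensemble, subset)
  out <- st$pairs
  out$D <- 1 - out$C
  out$G_bar <- 1 - out$E_bar
  out$RC <- rc$pairs$RC
  out[, c("sample_i", "sample_j", "C", "D", "E_bar", "G_bar", "ST", "RC")]
}
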