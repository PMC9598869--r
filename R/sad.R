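#' Generate a pseudo seed community from a lognormal SAD
#'
#' Draws relative abundances for `n_taxa` taxa from a lognormal species
#' abundance distribution and allocates exactly `n_individuals` individuals
#' to them with a single multinomial draw.  The location parameter of the
#' generating lognormal is set to `log(n_individuals / n_taxa) - sdlog^2 / 2`
#' so that the expected per-taxon abundance equals the community mean; with
#' the default `sdlog = 2.2` at the default scale (10^4 taxa, 10^8
#' organisms) the fitted parameters of the resulting counts are
#' meanlog ~ 6.8 and sdlog ~ 2.2, typical of environmental microbiomes.
#'
#' Because the community is declared to contain exactly `n_taxa` taxa, any
#' taxon left with zero individuals by the multinomial draw is repaired to
#' abundance 1 by moving one individual at a time from the currently most
#' abundant taxon; at realistic scale such repairs are vanishingly rare.
#'
#' @param n_taxa number of taxa (>= 2).
#' @param n_individuals total individuals (>= `n_taxa`).
#' @param sdlog standard deviation of the generating lognormal on the
#'   natural-log scale (>= 0).
#' @param rng_seed optional integer seed; the caller's RNG state is restored
#'   afterwards.
#' @return a [community()] of length `n_taxa` summing exactly to
#'   `n_individuals`, every abundance >= 1.
#' @seealso [fit_lognormal()], [perturb()]
#' @export
#' @examples
#' comm <- generate_pseudo_seed(100, 1e5, sdlog = 2.2, rng_seed = 1)
#' community_size(comm)
#' fit_lognormal(comm)
generate_pseudo_seed <- function(n_taxa, n_individuals, sdlog = 2.2,
                                 rng_seed = NULL) {
  stopifnot(n_taxa >= 2, n_taxa == floor(n_taxa),
            n_individuals == floor(n_individuals), sdlog >= 0)
  if (n_individuals < n_taxa)
    stop("n_individuals must be >= n_taxa so every taxon can hold one individual")
  meanlog <- log(n_individuals / n_taxa) - sdlog^2 / 2
  counts <- with_seed(rng_seed, {
    w <- rlnorm(n_taxa, meanlog = meanlog, sdlog = sdlog)
    as.double(rmultinom(1, size = n_individuals, prob = w / sum(w)))
  })
  # zero repair: donate single individuals from the current maximum
  while (any(counts == 0)) {
    z <- which(counts == 0)
    donor <- which.max(counts)
    take <- min(length(z), counts[donor] - 1)
    if (take < 1) stop("cannot repair zero-abundance taxa: community too small")
    counts[donor] <- counts[donor] - take
    counts[z[seq_len(take)]] <- 1
  }
  width <- max(5L, nchar(as.character(n_taxa)))
  community(counts, sprintf("t%0*d", width, seq_len(n_taxa)))
}

#' Perturb a community to mimic drift and dispersal limitation
#'
#' Applies two independent random perturbations to a community while
#' conserving its abundance multiset (and therefore its total size):
#'
#' * **rename**: `round(rename_fraction * n_taxa)` uniformly chosen taxa are
#'   relabelled with fresh, globally unique identifiers, mimicking drift
#'   producing taxa absent from the source community;
#' * **shuffle**: the abundances of `round(shuffle_fraction * n_taxa)`
#'   uniformly chosen taxa are permuted uniformly among that subset,
#'   mimicking dispersal limitation decoupling abundance from identity.
#'
#' @param base a [community()].
#' @param rename_fraction,shuffle_fraction proportions in `[0, 1]`.
#' @param rng_seed optional integer seed.
#' @param id_prefix prefix for the fresh identifiers of renamed taxa; make
#'   it unique per sample (e.g. the sample id) so that renamed taxa from
#'   different communities of a metacommunity never collide.
#' @return a perturbed [community()] with the same abundance multiset.
#' @export
#' @examples
#' comm <- community(c(a = 3, b = 2, c = 1))
#' perturb(comm, rename_fraction = 1, shuffle_fraction = 0, rng_seed = 1)
perturb <- function(base, rename_fraction = 0, shuffle_fraction = 0,
                    rng_seed = NULL, id_prefix = "x") {
  validate_community(base)
  if (rename_fraction < 0 || rename_fraction > 1 ||
      shuffle_fraction < 0 || shuffle_fraction > 1)
    stop("rename_fraction and shuffle_fraction must lie in [0, 1]")
  n <- length(base)
  ids <- names(base)
  ab <- unname(unclass(base))
  with_seed(rng_seed, {
    k_shuf <- round(shuffle_fraction * n)
    if (k_shuf >= 2) {
      sel <- sample.int(n, k_shuf)
      ab[sel] <- ab[sel][sample.int(k_shuf)]
    }
    k_ren <- round(rename_fraction * n)
    if (k_ren >= 1) {
      sel <- sample.int(n, k_ren)
      ids[sel] <- sprintf("new_%s_%06d", id_prefix, seq_len(k_ren))
    }
  })
  community(ab, ids)
}

#' Default perturbation design for a seed metacommunity
#'
#' Fifteen communities derived from one shared base pseudo seed with equal
#' rename and shuffle fractions increasing linearly from 0 to
#' `max_level`.  With the default `max_level = 0.6` the Bray-Curtis
#' dissimilarity of each community to its base spans ~0-0.8 and the mean
#' pairwise dissimilarity of the metacommunity is ~0.7, matching the spread
#' targeted by the simulation design (see the methods vignette).
#'
#' @param n_samples number of communities (default 15).
#' @param max_level largest rename/shuffle fraction (default 0.6).
#' @return a data frame with columns `rename` and `shuffle`.
#' @export
perturbation_design <- function(n_samples = 15, max_level = 0.6) {
  stopifnot(n_samples >= 2, max_level >= 0, max_level <= 1)
  lv <- max_level * (seq_len(n_samples) - 1) / (n_samples - 1)
  data.frame(rename = lv, shuffle = lv)
}

#' Assemble a seed metacommunity from perturbed pseudo seeds
#'
#' Perturbs each pseudo seed with its own specification and merges the
#' results into one sample x taxon count matrix over the union of all taxon
#' ids, filling absent taxa with zero.  Each sample consumes an independent
#' RNG substream derived from `rng_seed`, and renamed taxa are namespaced by
#' sample so identifiers never collide.
#'
#' @param pseudo_seeds list of [community()] objects, one per sample.  Pass
#'   the same community repeatedly (e.g. `rep(list(base), 15)`) to derive
#'   all samples from one shared base.
#' @param specs data frame with columns `rename` and `shuffle` (one row per
#'   seed), e.g. from [perturbation_design()].
#' @param rng_seed optional integer master seed for the assembly.
#' @return sample x taxon count matrix (samples `s01`, `s02`, ...).
#' @export
#' @examples
#' base <- generate_pseudo_seed(50, 5e4, rng_seed = 1)
#' mat <- build_seed_metacommunity(rep(list(base), 3),
#'                                 data.frame(rename = c(0, .2, .4),
#'                                            shuffle = c(0, .2, .4)),
#'                                 rng_seed = 1)
#' dim(mat)
build_seed_metacommunity <- function(pseudo_seeds, specs, rng_seed = NULL) {
  if (!is.list(pseudo_seeds) || !length(pseudo_seeds))
    stop("pseudo_seeds must be a non-empty list of communities")
  specs <- as.data.frame(specs)
  if (!all(c("rename", "shuffle") %in% names(specs)))
    stop("specs must have columns 'rename' and 'shuffle'")
  if (nrow(specs) != length(pseudo_seeds))
    stop("need exactly one spec per pseudo seed (",
         length(pseudo_seeds), " seeds, ", nrow(specs), " specs)")
  n <- length(pseudo_seeds)
  sample_ids <- sprintf("s%02d", seq_len(n))
  comms <- vector("list", n)
  for (i in seq_len(n)) {
    seed_i <- if (is.null(rng_seed)) NULL else derive_seed(rng_seed, "perturb", i)
    comms[[i]] <- perturb(pseudo_seeds[[i]],
                          rename_fraction = specs$rename[i],
                          shuffle_fraction = specs$shuffle[i],
                          rng_seed = seed_i, id_prefix = sample_ids[i])
  }
  universe <- unique(unlist(lapply(comms, names), use.names = FALSE))
  mat <- matrix(0, nrow = n, ncol = length(universe),
                dimnames = list(sample_ids, universe))
  for (i in seq_len(n)) mat[i, names(comms[[i]])] <- unclass(comms[[i]])
  mat
}

#' Maximum-likelihood lognormal fit to community abundances
#'
#' Fits a lognormal distribution to the positive abundances of a community
#' by the closed-form MLE on natural logs: `meanlog` is the mean of the log
#' abundances and `sdlog` their population (1/n) standard deviation.  Zeros
#' carry no information on the log scale and are excluded; the number of
#' positive counts used is returned alongside.
#'
#' @param x a [community()] or any numeric vector of counts.
#' @return a list of class `"lognormal_fit"` with elements `meanlog`,
#'   `sdlog` and `n_positive`.
#' @export
#' @examples
#' fit_lognormal(c(1, exp(2))) # meanlog 1, sdlog 1
fit_lognormal <- function(x) {
  x <- as.double(unclass(x))
  pos <- x[x > 0]
  if (length(pos) < 2)
    stop("need at least 2 positive abundances to fit a lognormal")
  lx <- log(pos)
  m <- mean(lx)
  structure(list(meanlog = m, sdlog = sqrt(mean((lx - m)^2)),
                 n_positive = length(pos)),
            class = "lognormal_fit")
}

#' @export
print.lognormal_fit <- function(x, ...) {
  cat(sprintf("lognormal fit: meanlog = %.3f, sdlog = %.3f (n = %d positive)\n",
              x$meanlog, x$sdlog, x$n_positive))
  invisible(x)
}
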