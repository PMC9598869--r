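# Independent oracles and shared fixtures, kept deliberately naive: they
# must not reuse any code path they are checking.

# closed-form Bray-Curtis, written out long-hand
naive_bray <- function(x, y) {
  s <- 0
  for (k in seq_along(x)) s <- s + min(x[k], y[k])
  1 - 2 * s / (sum(x) + sum(y))
}

# double-loop pairwise Bray-Curtis
naive_pairwise <- function(mat) {
  n <- nrow(mat)
  out <- NULL
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n))
    out <- rbind(out, data.frame(sample_i = rownames(mat)[i],
                                 sample_j = rownames(mat)[j],
                                 bc = naive_bray(mat[i, ], mat[j, ])))
  out
}

# exact per-taxon inclusion probabilities of k successive weighted draws
# without replacement (full enumeration; tiny pools only)
exact_occupancy_prob <- function(w, k) {
  incl <- numeric(length(w))
  rec <- function(avail, p, chosen) {
    if (length(chosen) == k) {
      incl[chosen] <<- incl[chosen] + p
      return(invisible())
    }
    for (i in avail) rec(setdiff(avail, i), p * w[i] / sum(w[avail]),
                         c(chosen, i))
  }
  rec(seq_along(w), 1, integer(0))
  incl
}

# a small reproducible metacommunity for module-level tests
toy_metacommunity <- function(seed = 7, n_taxa = 500, n_individuals = 5e5,
                              n_samples = 8) {
  base <- generate_pseudo_seed(n_taxa, n_individuals, sdlog = 2.2,
                               rng_seed = derive_seed(seed, "toy_base"))
  build_seed_metacommunity(rep(list(base), n_samples),
                           perturbation_design(n_samples, 0.6),
                           rng_seed = derive_seed(seed, "toy_meta"))
}

random_count_matrix <- function(seed, n_samples = 5, n_taxa = 7, lambda = 4) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    m <- matrix(rpois(n_samples * n_taxa, lambda), n_samples, n_taxa,
                dimnames = list(sprintf("s%02d", 1:n_samples),
                                sprintf("t%05d", 1:n_taxa)))
    m[rowSums(m) == 0, 1] <- 1
    m
  })
}
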