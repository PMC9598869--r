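test_that("generate_pseudo_seed conserves totals, richness and handles the minimal case", {
  comm <- generate_pseudo_seed(100, 1e5, sdlog = 2.2, rng_seed = 1)
  expect_length(comm, 100)
  expect_equal(community_size(comm), 1e5)
  expect_true(all(unclass(comm) >= 1))

  # minimal total with flat weights: every taxon gets exactly one individual
  tiny <- generate_pseudo_seed(5, 5, sdlog = 0, rng_seed = 7)
  expect_equal(unname(unclass(tiny)), rep(1, 5))

  expect_error(generate_pseudo_seed(10, 5), "n_individuals")
})

test_that("fit_lognormal matches hand calculations and the MASS MLE", {
  f <- fit_lognormal(c(exp(1), exp(1), exp(1)))
  expect_equal(f$meanlog, 1)
  expect_equal(f$sdlog, 0)

  f <- fit_lognormal(c(1, exp(2))) # logs 0 and 2
  expect_equal(f$meanlog, 1)
  expect_equal(f$sdlog, 1)

  expect_error(fit_lognormal(c(0, 0, 5)), "positive")

  set.seed(42)
  x <- rlnorm(500, meanlog = 3, sdlog = 1.4)
  f <- fit_lognormal(x)
  o <- MASS::fitdistr(x, "lognormal")
  expect_equal(f$meanlog, unname(o$estimate["meanlog"]), tolerance = 1e-8)
  expect_equal(f$sdlog, unname(o$estimate["sdlog"]), tolerance = 1e-8)
})

test_that("fit_lognormal recovers generating parameters within 3 standard errors", {
  set.seed(9)
  n <- 1e4; mu <- 2; sd <- 1.5
  f <- fit_lognormal(rlnorm(n, mu, sd))
  expect_lt(abs(f$meanlog - mu), 3 * sd / sqrt(n))
  expect_lt(abs(f$sdlog - sd), 3 * sd / sqrt(2 * n))
})

test_that("lognormal mean identity holds for generated seed communities", {
  # E[abundance] = exp(meanlog + sdlog^2/2): the fitted parameters of a
  # generated community must reproduce log(n_individuals / n_taxa)
  comm <- generate_pseudo_seed(5000, 5e7, sdlog = 2.2, rng_seed = 11)
  f <- fit_lognormal(comm)
  expect_lt(abs(f$meanlog + f$sdlog^2 / 2 - log(5e7 / 5000)), 0.2)
})

test_that("perturb conserves the abundance multiset and hits its limit cases", {
  base <- generate_pseudo_seed(200, 2e4, rng_seed = 3)

  same <- perturb(base, 0, 0, rng_seed = 1)
  expect_identical(unclass(same), unclass(base))
  expect_equal(naive_bray(unclass(base), unclass(same)), 0)

  renamed <- perturb(base, 1, 0, rng_seed = 2)
  expect_length(intersect(names(base), names(renamed)), 0)
  expect_equal(sort(unclass(renamed)), sort(unclass(base)), ignore_attr = TRUE)

  for (s in 1:20) {
    p <- perturb(base, runif(1), runif(1), rng_seed = s)
    expect_equal(sort(unname(unclass(p))), sort(unname(unclass(base))))
    expect_equal(community_size(p), community_size(base))
  }

  expect_error(perturb(base, 1.5, 0), "\\[0, 1\\]")
})

test_that("full shuffle of a 3-taxon community matches exhaustive enumeration", {
  base <- community(c(a = 3, b = 2, c = 1))
  perms <- list(c(3, 2, 1), c(3, 1, 2), c(2, 3, 1), c(2, 1, 3),
                c(1, 3, 2), c(1, 2, 3))
  expected_bc <- vapply(perms, function(p) naive_bray(c(3, 2, 1), p), numeric(1))
  expected_tab <- table(round(expected_bc, 10)) / 6

  n <- 1200
  got <- vapply(seq_len(n), function(s) {
    p <- perturb(base, 0, 1, rng_seed = s)
    naive_bray(unclass(base), unclass(p)[names(base)])
  }, numeric(1))
  got_tab <- table(factor(round(got, 10), levels = names(expected_tab))) / n
  # each permutation equally likely: empirical BC distribution ~ enumeration
  chi <- suppressWarnings(chisq.test(table(factor(round(got, 10),
                                                  levels = names(expected_tab))),
                                     p = as.numeric(expected_tab)))
  expect_gt(chi$p.value, 0.001)
  expect_equal(as.numeric(got_tab), as.numeric(expected_tab), tolerance = 0.15)
})

test_that("perturbation dissimilarity grows with the rename fraction", {
  base <- generate_pseudo_seed(200, 2e4, rng_seed = 5)
  levels <- c(0, 0.25, 0.5, 0.75, 1)
  mean_bc <- vapply(levels, function(f) {
    mean(vapply(1:20, function(s) {
      p <- perturb(base, f, 0, rng_seed = derive_seed(s, "mono", f))
      u <- union(names(base), names(p))
      x <- setNames(numeric(length(u)), u); y <- x
      x[names(base)] <- unclass(base); y[names(p)] <- unclass(p)
      naive_bray(x, y)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_bc) >= 0))
  expect_equal(mean_bc[1], 0)
  expect_equal(mean_bc[5], 1)
})

test_that("build_seed_metacommunity merges perturbed seeds over the taxon union", {
  base <- generate_pseudo_seed(100, 1e4, rng_seed = 2)

  flat <- build_seed_metacommunity(rep(list(base), 4),
                                   data.frame(rename = 0, shuffle = 0)[rep(1, 4), ],
                                   rng_seed = 1)
  expect_equal(nrow(unique(flat)), 1) # identical rows
  expect_equal(mean(pairwise_beta(flat)$pairs$bray_curtis), 0)

  two <- build_seed_metacommunity(rep(list(base), 2),
                                  data.frame(rename = c(0, 1), shuffle = 0),
                                  rng_seed = 1)
  expect_equal(ncol(two), 200) # disjoint rename doubles the taxon pool

  expect_error(build_seed_metacommunity(rep(list(base), 3),
                                        data.frame(rename = 0, shuffle = 0)),
               "one spec per pseudo seed")

  # default design: dissimilarity positive but below saturation, and the
  # emitted matrix is self-consistent against an independent recomputation
  meta <- toy_metacommunity(seed = 31, n_taxa = 200, n_individuals = 2e4,
                            n_samples = 5)
  pb <- pairwise_beta(meta)
  oracle <- naive_pairwise(meta)
  expect_equal(pb$pairs$bray_curtis, oracle$bc, tolerance = 1e-12)
  expect_gt(pb$mean, 0)
  expect_lt(pb$mean, 1)
})
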