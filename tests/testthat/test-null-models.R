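test_that("build_regional_pool computes frequencies and pooled abundances", {
  m <- rbind(s1 = c(t1 = 4, t2 = 2, t3 = 0, t4 = 0),
             s2 = c(t1 = 2, t2 = 0, t3 = 1, t4 = 0))
  pool <- build_regional_pool(m)
  expect_equal(pool$taxon_ids, c("t1", "t2", "t3")) # all-zero column dropped
  expect_equal(pool$frequency, c(2, 1, 1))
  expect_equal(pool$relative_abundance, c(6, 2, 1) / 9)
  expect_equal(sum(pool$relative_abundance), 1)
})

test_that("weighted occupancy matches exhaustively enumerated probabilities", {
  draw_inclusion <- function(w, k, n_draws) {
    counts <- numeric(length(w))
    for (s in seq_len(n_draws)) {
      set.seed(s)
      idx <- stochsim:::sample_occupancy(w, k)
      counts[idx] <- counts[idx] + 1
    }
    counts / n_draws
  }
  n <- 4000
  # equal frequencies, draw 2 of 3: every taxon occupied w.p. 2/3
  p_eq <- exact_occupancy_prob(c(1, 1, 1), 2)
  expect_equal(p_eq, rep(2 / 3, 3))
  emp <- draw_inclusion(c(1, 1, 1), 2, n)
  expect_true(all(abs(emp - p_eq) < 3 * sqrt(p_eq * (1 - p_eq) / n)))
  # unequal frequencies: successive weighted draws, enumerated
  w <- c(3, 2, 1, 1)
  p_uneq <- exact_occupancy_prob(w, 2)
  emp <- draw_inclusion(w, 2, n)
  expect_true(all(abs(emp - p_uneq) < 3 * sqrt(p_uneq * (1 - p_uneq) / n)))
})

test_that("randomize_shuffle conserves richness, totals and abundance multisets", {
  m <- random_count_matrix(5, n_samples = 4, n_taxa = 6)
  for (s in 1:25) {
    nm <- randomize_shuffle(m, rng_seed = s)
    expect_equal(rowSums(nm), rowSums(m))
    expect_equal(rowSums(nm > 0), rowSums(m > 0))
    for (i in seq_len(nrow(m)))
      expect_equal(sort(nm[i, nm[i, ] > 0]), sort(m[i, m[i, ] > 0]),
                   ignore_attr = TRUE)
  }
  # forced occupancy: one sample occupying the whole pool
  one <- rbind(s1 = c(t1 = 5, t2 = 2, t3 = 1))
  nm <- randomize_shuffle(one, rng_seed = 3)
  expect_equal(sort(nm[1, ]), sort(one[1, ]), ignore_attr = TRUE)
})

test_that("randomize_proportional fills occupancy from regional abundances", {
  # forced single occupied taxon receives the full total
  m1 <- rbind(s1 = c(t1 = 17))
  expect_equal(randomize_proportional(m1, rng_seed = 1)[1, 1], 17)

  # two occupied taxa with regional shares 0.9 / 0.1, total 1002:
  # expected 1 + 1000 * share each; empirical means within 3 SE
  m2 <- rbind(s1 = c(t1 = 901, t2 = 101), s2 = c(t1 = 899, t2 = 103))
  pool <- build_regional_pool(m2)
  expect_equal(pool$relative_abundance, c(0.9, 0.1), tolerance = 0.01)
  n <- 1000
  acc <- c(0, 0)
  for (s in seq_len(n)) acc <- acc + randomize_proportional(m2, rng_seed = s)[1, ]
  expected <- 1 + 1000 * pool$relative_abundance
  se <- sqrt(1000 * pool$relative_abundance * (1 - pool$relative_abundance) / n)
  expect_true(all(abs(acc / n - expected) < 3 * se))

  # occupied taxa always end with >= 1 individual, richness/totals fixed
  m <- random_count_matrix(6, n_samples = 4, n_taxa = 6)
  for (s in 1:25) {
    nm <- randomize_proportional(m, rng_seed = s)
    expect_equal(rowSums(nm), rowSums(m))
    expect_equal(rowSums(nm > 0), rowSums(m > 0))
    expect_true(all(nm[nm > 0] >= 1))
  }
})

test_that("generate_ensemble is deterministic and conserves invariants", {
  m <- random_count_matrix(8, n_samples = 3, n_taxa = 4)
  e1 <- generate_ensemble(m, "shuffle", iterations = 1, rng_seed = 5)
  expect_equal(nrow(e1$null_bc), 1)

  e2 <- generate_ensemble(m, "proportional", iterations = 50, rng_seed = 5)
  e3 <- generate_ensemble(m, "proportional", iterations = 50, rng_seed = 5)
  expect_identical(e2$null_bc, e3$null_bc)

  full <- generate_ensemble(m, "shuffle", iterations = 1000, rng_seed = 2,
                            keep_matrices = TRUE)
  for (nm in full$matrices) {
    expect_equal(rowSums(nm > 0), rowSums(m > 0))
    expect_equal(rowSums(nm), rowSums(m))
  }
})

test_that("the two randomization schemes bracket the observed dissimilarity", {
  meta <- toy_metacommunity(seed = 23)
  mock <- subsample_matrix(meta, 3000, rng_seed = 1)
  obs <- pairwise_beta(mock)$mean
  sh <- generate_ensemble(mock, "shuffle", iterations = 30, rng_seed = 2)
  pr <- generate_ensemble(mock, "proportional", iterations = 30, rng_seed = 3)
  # shuffle scatters abundance over the pool: highly dissimilar nulls;
  # proportional refills from one regional profile: similar nulls
  expect_gt(mean(sh$null_bc), obs)
  expect_lt(mean(pr$null_bc), obs)
  expect_gt(mean(sh$null_bc), mean(pr$null_bc))
})
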