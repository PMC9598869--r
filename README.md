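# stochsim

Microbial community profiles are random subsamples: a gram of soil holds
~10^4 prokaryotic taxa and ~10^8 organisms, while a sequencing library
captures at most a few hundred thousand reads.  This undersampling is known
to inflate β-diversity (Bray–Curtis dissimilarity between samples), and
because community-assembly stochasticity is inferred by comparing observed
β-diversity against null-model expectations, the inflation propagates into
the inference itself.

`stochsim` is a simulation pipeline for measuring that propagation under
fully controlled conditions.  It is aimed at microbial ecologists who use
null-model stochasticity metrics and want to know how much of their signal
random sampling alone can produce.  The package:

* generates **seed metacommunities** at full environmental scale from a
  lognormal species abundance distribution (15 communities derived from one
  base by renaming taxa and shuffling abundances, mimicking drift and
  dispersal limitation);
* **rarefies** them without replacement (multivariate hypergeometric) to
  sequencing depths of 5,000–200,000 reads;
* partitions each matrix into **abundant** (top taxa holding 80% of the
  total relative abundance) and **rare** subcommunities;
* generates **null ensembles** under two randomization schemes that both
  fix per-sample richness and draw occupancy frequency-weighted from the
  regional pool: *shuffle* (permutes each sample's abundances; dissimilar
  nulls) and *proportional* (refills from regional relative abundances;
  similar nulls);
* computes two stochasticity statistics per sample pair, with observed
  similarity `C` and mean null similarity `Ē`:

  ```
  ST = Ē / C            if Ē < C
  ST = (1 − Ē) / (1 − C) if Ē ≥ C          (stochastic ratio, in [0, 1])

  RC = 2 ((n_less + ½ n_equal) / n_iter − ½)   (Raup–Crick, in [−1, 1])
  ```

* and contrasts every statistic between the full-scale seed reference and
  its undersampled mock profiles, per depth, subcommunity and method.

The metrics also accept user-supplied sample × taxon tables (plain TSV via
`read_count_table()`, optionally BIOM via the Bioconductor *biomformat*
package), so they are reusable on real data.

## Worked example

```r
library(stochsim)

## a full-scale seed community: 10^4 taxa, 10^8 organisms, lognormal SAD
base <- generate_pseudo_seed(1e4, 1e8, sdlog = 2.2, rng_seed = 1)
fit_lognormal(base)
#> lognormal fit: meanlog = 6.827, sdlog = 2.237 (n = 10000 positive)

## rarefy it to a realistic 30,000-read profile
mock <- subsample(base, 30000, rng_seed = 2)
fit_lognormal(mock)
#> lognormal fit: meanlog = 1.039, sdlog = 1.145 (n = 3872 positive)
unlist(capture_stats(base, mock))
#> observed_taxa     lost_taxa
#>          3872          6128

## 15-sample metacommunity and its depth-5,000 mock profile
meta <- build_seed_metacommunity(rep(list(base), 15), perturbation_design(),
                                 rng_seed = 3)
m5 <- subsample_matrix(meta, 5000, rng_seed = 4)
pairwise_beta(meta)$mean   # 0.699  (full-scale truth)
pairwise_beta(m5)$mean     # 0.800  (inflated by undersampling)

## null ensembles bracket the observed dissimilarity
sh <- generate_ensemble(m5, "shuffle",      iterations = 100, rng_seed = 5)
pr <- generate_ensemble(m5, "proportional", iterations = 100, rng_seed = 6)
mean(sh$null_bc)           # 0.909  (dissimilar nulls, above observed)
mean(pr$null_bc)           # 0.724  (similar nulls, below observed)

## stochasticity metrics against the proportional nulls
stochastic_ratio(m5, pr)$mean_st          # 0.818
unlist(rc_bray(m5, pr)$classification)
#>      frac_above      frac_below frac_stochastic
#>       0.695           0.162           0.143
```

The numbers read as follows: rarefaction to 30,000 reads loses 6,128 of the
10,000 taxa (all rare) and compresses the fitted SAD from
meanlog/sdlog ≈ 6.8/2.2 to ≈ 1.0/1.1; at a depth of 5,000 the mean pairwise
Bray–Curtis rises from 0.70 to 0.80; the two null schemes land on opposite
sides of the observed value, and a mean stochastic ratio of 0.82 against
proportional nulls says the undersampled profiles look far more
"stochastic" than the full-scale truth they came from (the seed
metacommunity's own value is ~0.6).

The full factorial experiment (all depths × {whole, abundant, rare} ×
both methods, plus the seed reference) is one call:

```r
res <- run_experiment(experiment_config(iterations = 100, master_seed = 1))
res$summary                    # tidy per (depth x subset x method) table
compare_seed_vs_mock(res)      # overestimation deltas and depth trends
```

A thin command-line wrapper is installed at
`inst/scripts/run_experiment.R` (`--config`, `--depths`, `--null-method`,
`--iterations`, `--replicates`, `--seed`, `--out`).

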