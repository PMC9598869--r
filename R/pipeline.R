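#' Configuration of a full undersampling experiment
#'
#' Bundles every knob of the simulation study.  The defaults are the
#' standard study conditions: 15 communities of 10^4 taxa and 10^8
#' organisms drawn from a lognormal SAD (sdlog 2.2), perturbation levels
#' spanning 0-0.6 per axis, sequencing depths from 5,000 to 200,000, both
#' null-model methods at 1,000 iterations, and an 80% abundant/rare
#' threshold.  Use `iterations = 100` as the fast profile for interactive
#' work; the Monte-Carlo error of the mean stochastic ratio between 100 and
#' 1,000 iterations is well below 0.02.
#'
#' @param n_taxa,n_individuals,sdlog seed-community scale and SAD shape.
#' @param n_samples number of communities in the metacommunity.
#' @param max_perturbation largest rename/shuffle fraction of the design
#'   (see [perturbation_design()]).
#' @param depths sequencing depths (strictly increasing positive integers).
#' @param methods null-model methods to run.
#' @param iterations null communities per ensemble.
#' @param abundant_threshold cumulative relative-abundance cutoff.
#' @param master_seed integer master seed; every stage derives its own
#'   substream via [derive_seed()].
#' @param replicates number of independent replicate runs for
#'   [run_replicates()].
#' @param output_dir optional directory where [run_experiment()] writes its
#'   result tables as CSV/TSV.
#' @return list of class `"experiment_config"`.
#' @export
experiment_config <- function(n_taxa = 1e4, n_individuals = 1e8, sdlog = 2.2,
                              n_samples = 15, max_perturbation = 0.6,
                              depths = c(5000, 10000, 30000, 50000, 70000,
                                         100000, 200000),
                              methods = c("shuffle", "proportional"),
                              iterations = 1000, abundant_threshold = 0.80,
                              master_seed = 1, replicates = 1,
                              output_dir = NULL) {
  depths <- as.numeric(depths)
  if (any(diff(depths) <= 0) || any(depths <= 0))
    stop("depths must be strictly increasing positive integers")
  if (max(depths) > n_individuals) stop("depths exceed the seed community size")
  methods <- match.arg(methods, c("shuffle", "proportional"), several.ok = TRUE)
  structure(list(n_taxa = n_taxa, n_individuals = n_individuals, sdlog = sdlog,
                 n_samples = n_samples, max_perturbation = max_perturbation,
                 depths = depths, methods = methods, iterations = iterations,
                 abundant_threshold = abundant_threshold,
                 master_seed = master_seed, replicates = replicates,
                 output_dir = output_dir),
            class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf(paste0("experiment config: %d samples x (%g taxa, %g organisms), ",
                     "sdlog %.2f, depths %s, %d iterations, seed %d\n"),
              x$n_samples, x$n_taxa, x$n_individuals, x$sdlog,
              paste(x$depths, collapse = "/"), x$iterations, x$master_seed))
  invisible(x)
}

#' Round-trip a configuration through YAML
#'
#' @param config an [experiment_config()].
#' @param path file path.
#' @return `read_config()`: the [experiment_config()] stored at `path`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- yaml::yaml.load_file(path)
  do.call(experiment_config, vals[!vapply(vals, is.null, logical(1))])
}

# analysis of one count matrix: beta, null beta, ST, RC per subset x method
analyse_matrix <- function(mat, config, label, seed_stage) {
  part <- partition_abundant_rare(mat, config$abundant_threshold)
  subsets <- list(whole = NULL, abundant = part$abundant, rare = part$rare)
  rows <- list()
  for (sname in names(subsets)) {
    sub <- if (is.null(subsets[[sname]])) mat
           else subset_taxa(mat, subsets[[sname]], drop_empty_taxa = TRUE)
    keep <- rowSums(sub) > 0
    if (sum(keep) < 2) {
      warning("subset '", sname, "' of ", label, " has < 2 non-empty samples; skipped")
      next
    }
    if (!all(keep))
      warning("subset '", sname, "' of ", label, ": excluding empty sample(s) ",
              paste(rownames(sub)[!keep], collapse = ", "))
    sub <- sub[keep, , drop = FALSE]
    obs_beta <- mean(pairwise_bc(sub))
    mean_rich <- mean(rowSums(sub > 0))
    for (method in config$methods) {
      ens <- generate_ensemble(sub, method, iterations = config$iterations,
                               rng_seed = derive_seed(config$master_seed,
                                                      seed_stage, sname, method))
      st <- stochastic_ratio(sub, ens)
      rc <- rc_bray(sub, ens)
      rows[[length(rows) + 1]] <- data.frame(
        matrix_id = label, subset = sname, method = method,
        n_samples = nrow(sub), mean_richness = mean_rich,
        observed_beta = obs_beta, null_beta = mean(ens$null_bc),
        mean_st = st$mean_st,
        frac_above = rc$classification$frac_above,
        frac_below = rc$classification$frac_below,
        frac_stochastic = rc$classification$frac_stochastic,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Run the full undersampling experiment
#'
#' Executes the whole simulation: generate the base pseudo seed, assemble
#' the perturbed seed metacommunity, rarefy it to every configured depth,
#' partition each matrix into abundant/rare subcommunities, generate null
#' ensembles under each method, and compute observed beta, null beta, mean
#' stochastic ratio and Raup-Crick classification fractions for every
#' (matrix x subset x method) cell.  The seed metacommunity itself is
#' analysed at full scale (no subsampling) and labelled `"seed"`; it is the
#' reference against which the mock rows measure the effect of random
#' sampling.  Fully reproducible from the config's master seed.
#'
#' @param config an [experiment_config()].
#' @return list of class `"experiment_result"`: `summary` (tidy data frame,
#'   one row per matrix x subset x method, with a `depth` column that is
#'   `NA` for the seed reference), `richness` (per depth x sample observed
#'   richness), and `config`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  ms <- config$master_seed
  base <- generate_pseudo_seed(config$n_taxa, config$n_individuals,
                               config$sdlog,
                               rng_seed = derive_seed(ms, "pseudo_seed"))
  design <- perturbation_design(config$n_samples, config$max_perturbation)
  meta <- build_seed_metacommunity(rep(list(base), config$n_samples), design,
                                   rng_seed = derive_seed(ms, "metacommunity"))
  matrices <- c(list(seed = meta),
                setNames(lapply(config$depths, function(d)
                  subsample_matrix(meta, d, rng_seed = derive_seed(ms, "depth", d))),
                  as.character(config$depths)))
  summary_rows <- list()
  richness_rows <- list()
  for (label in names(matrices)) {
    m <- matrices[[label]]
    summary_rows[[label]] <- analyse_matrix(m, config, label,
                                            seed_stage = paste0("nulls_", label))
    richness_rows[[label]] <- data.frame(
      matrix_id = label, sample = rownames(m), richness = rowSums(m > 0),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  summary <- do.call(rbind, summary_rows)
  rownames(summary) <- NULL
  summary$depth <- suppressWarnings(as.numeric(summary$matrix_id))
  richness <- do.call(rbind, richness_rows)
  rownames(richness) <- NULL
  result <- structure(list(summary = summary, richness = richness,
                           config = config),
                      class = "experiment_result")
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(summary, file.path(config$output_dir, "summary.csv"),
                     row.names = FALSE)
    utils::write.csv(richness, file.path(config$output_dir, "richness.csv"),
                     row.names = FALSE)
    write_count_table(meta, file.path(config$output_dir, "seed_metacommunity.tsv"))
  }
  result
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("experiment result: %d summary rows (%d matrices)\n",
              nrow(x$summary), length(unique(x$summary$matrix_id))))
  invisible(x)
}

#' Replicate runs of the experiment
#'
#' Runs [run_experiment()] `config$replicates` times with independent
#' master seeds derived from the config's seed and stacks the summaries.
#'
#' @param config an [experiment_config()].
#' @return data frame: the per-replicate summaries with a `replicate` column.
#' @export
run_replicates <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  out <- lapply(seq_len(config$replicates), function(r) {
    cfg <- config
    cfg$master_seed <- derive_seed(config$master_seed, "replicate", r)
    cfg$output_dir <- NULL
    s <- run_experiment(cfg)$summary
    s$replicate <- r
    s
  })
  do.call(rbind, out)
}

#' Seed-vs-mock overestimation table
#'
#' Quantifies the effect of random sampling by differencing every mock row
#' of an experiment summary against the seed reference row of the same
#' subset (and method):  `delta_beta` = mock observed beta - seed observed
#' beta, `delta_st` = mock mean ST - seed mean ST.  A per (subset x method)
#' trend summary reports the Kendall correlation of each delta with depth
#' (negative values mean the bias eases as sequencing deepens).
#'
#' @param result an [run_experiment()] result.
#' @return list with `table` (per depth x subset x method deltas) and
#'   `trend` (per subset x method Kendall tau of delta vs depth).
#' @export
compare_seed_vs_mock <- function(result) {
  stopifnot(inherits(result, "experiment_result"))
  s <- result$summary
  seed_rows <- s[s$matrix_id == "seed", ]
  if (!nrow(seed_rows)) stop("result lacks the seed reference rows")
  mock <- s[s$matrix_id != "seed", ]
  key <- function(df) paste(df$subset, df$method)
  ref <- seed_rows[match(key(mock), key(seed_rows)), ]
  tab <- data.frame(depth = mock$depth, subset = mock$subset,
                    method = mock$method,
                    delta_beta = mock$observed_beta - ref$observed_beta,
                    delta_st = mock$mean_st - ref$mean_st,
                    stringsAsFactors = FALSE)
  trend <- do.call(rbind, lapply(split(tab, key(tab)), function(g) {
    data.frame(subset = g$subset[1], method = g$method[1],
               tau_beta = stats::cor(g$depth, g$delta_beta, method = "kendall"),
               tau_st = stats::cor(g$depth, g$delta_st, method = "kendall"),
               stringsAsFactors = FALSE)
  }))
  rownames(trend) <- NULL
  list(table = tab, trend = trend)
}
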