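#' Finite-depth genotyping of a cohort
#'
#' Emulates genotyping a random subset of a cohort: a multinomial draw of
#' size `n` from the true genotype proportions.
#'
#' @param true_props Genotype proportions (AA, AB, BB), summing to 1.
#' @param n Number of individuals genotyped.
#' @return Named integer counts summing to `n`.
#' @export
sample_genotyping <- function(true_props, n) {
  pr <- named_geno(true_props)
  if (any(pr < 0) || abs(sum(pr) - 1) > 1e-9)
    stop("true proportions must be non-negative and sum to 1")
  if (n < 1) stop("genotyping depth must be >= 1")
  stats::setNames(as.integer(stats::rmultinom(1, n, pr)), GENOTYPES)
}

#' Specification of a synthetic genotyping experiment
#'
#' Describes an experiment-like dataset: the generating parameters, the
#' number of replicate populations, and the genotyping depth ranges per
#' stage (defaults match the laboratory experiment: 28-51 eggs and 40-95
#' adults genotyped per replicate and generation).
#'
#' @param fitness,development,habitat Generating parameter objects
#'   (defaults: the laboratory set).
#' @param cfg A [sim_config()] for the underlying populations.
#' @param n_replicates Number of replicate populations.
#' @param eggs_depth,adults_depth Length-2 integer ranges for the number
#'   genotyped per replicate and generation.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(fitness = lab_fitness(),
                           development = lab_development(),
                           habitat = lab_habitat(),
                           cfg = sim_config(K = 1000, n_generations = 5,
                                            p0 = 0.32, seed = 1L),
                           n_replicates = 4,
                           eggs_depth = c(28, 51),
                           adults_depth = c(40, 95)) {
  check_depth <- function(d, what) {
    if (length(d) != 2 || any(d < 1) || d[1] > d[2])
      stop(what, " genotyping depth must be a valid range >= 1")
  }
  check_depth(eggs_depth, "egg"); check_depth(adults_depth, "adult")
  structure(list(fitness = fitness, development = development,
                 habitat = habitat, cfg = cfg,
                 n_replicates = as.integer(n_replicates),
                 eggs_depth = as.integer(eggs_depth),
                 adults_depth = as.integer(adults_depth)),
            class = "synthetic_spec")
}

#' Generate an experiment-like genotype count dataset
#'
#' Runs the individual-based model for each replicate population and
#' genotypes a random subset of eggs and adults at every generation:
#' eggs are sex-pooled (eggs cannot be sexed), adults record sex. The
#' genotyping depth per replicate and generation is drawn uniformly from
#' the configured ranges. Returns both the observed counts and the
#' underlying complete trajectories as ground truth.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Optional integer overriding `spec$cfg$seed`.
#' @return A list with `counts` (a genotype count table: `replicate`,
#'   `generation`, `stage`, `sex`, `genotype`, `count`) and `truth` (list
#'   of `trajectory` objects, one per replicate). Extinct replicates
#'   yield a partial table.
#' @export
make_experiment_dataset <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  master <- seed %||% spec$cfg$seed
  sim_seeds <- derive_seeds(master, seq_len(spec$n_replicates))
  obs_seeds <- derive_seeds(master, 500L + seq_len(spec$n_replicates))
  rows <- list()
  truth <- vector("list", spec$n_replicates)
  for (r in seq_len(spec$n_replicates)) {
    tr <- run_simulation(spec$cfg, spec$fitness, spec$development,
                         spec$habitat, seed = sim_seeds[r])
    truth[[r]] <- tr
    set.seed(obs_seeds[r])
    rep_id <- sprintf("R%02d", r)
    for (g in sort(unique(tr$records$generation))) {
      gr <- tr$records[tr$records$generation == g, ]
      ## eggs: pooled over sex
      eggs <- counts_from_table(gr[gr$stage == "egg", ])
      if (sum(eggs) > 0) {
        depth <- sample(spec$eggs_depth[1]:spec$eggs_depth[2], 1)
        cnt <- sample_genotyping(eggs / sum(eggs), min(depth, sum(eggs)))
        rows[[length(rows) + 1L]] <- data.frame(
          replicate = rep_id, generation = g, stage = "egg",
          sex = "unknown", genotype = GENOTYPES, count = as.integer(cnt),
          stringsAsFactors = FALSE)
      }
      ## adults: sexed; split the genotyped sample by the true sex ratio
      ad <- gr[gr$stage == "adult", ]
      if (sum(ad$count) > 0) {
        depth <- sample(spec$adults_depth[1]:spec$adults_depth[2], 1)
        depth <- min(depth, sum(ad$count))
        cell_props <- ad$count / sum(ad$count)
        cnt <- as.integer(stats::rmultinom(1, depth, cell_props))
        rows[[length(rows) + 1L]] <- data.frame(
          replicate = rep_id, generation = g, stage = "adult",
          sex = ad$sex, genotype = ad$genotype, count = cnt,
          stringsAsFactors = FALSE)
      }
    }
  }
  list(counts = do.call(rbind, rows), truth = truth)
}
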