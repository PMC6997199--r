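#' Normalized root-mean-squared error between two series
#'
#' RMSE between an observed and a simulated series, normalized by the mean
#' of the observed series (`norm = "mean"`, the default, stable for short
#' proportion series) or by its range (`norm = "range"`).
#'
#' @param observed,simulated Equal-length numeric series.
#' @param norm `"mean"` or `"range"`.
#' @return A non-negative number; 0 iff the series are identical.
#' @examples
#' nrmse(c(0.2, 0.4, 0.6), c(0.3, 0.5, 0.7))   # 0.25
#' @export
nrmse <- function(observed, simulated, norm = c("mean", "range")) {
  norm <- match.arg(norm)
  if (length(observed) != length(simulated) || length(observed) < 1)
    stop("series must have equal, positive length")
  rmse <- sqrt(mean((observed - simulated)^2))
  denom <- if (norm == "mean") mean(observed) else diff(range(observed))
  if (denom == 0) stop("observed series has zero ", norm, "; nRMSE undefined")
  rmse / denom
}

## The six fitted variables: genotype proportions in eggs and adults,
## generations 1..G, pooled over sex, as a generations x 6 matrix.
trajectory_variables <- function(traj, generations) {
  out <- matrix(NA_real_, length(generations), 6,
                dimnames = list(NULL, paste(rep(c("egg", "adult"), each = 3),
                                            GENOTYPES, sep = "_")))
  for (stage in c("egg", "adult")) {
    pr <- stage_proportions(traj, stage)
    for (g in GENOTYPES) {
      v <- pr[pr$genotype == g, ]
      idx <- match(generations, v$generation)
      out[, paste(stage, g, sep = "_")] <- v$proportion[idx]
    }
  }
  out
}

recursion_variables <- function(rec, generations) {
  out <- matrix(NA_real_, length(generations), 6,
                dimnames = list(NULL, paste(rep(c("egg", "adult"), each = 3),
                                            GENOTYPES, sep = "_")))
  for (stage in c("egg", "adult")) {
    for (g in GENOTYPES) {
      v <- rec[rec$stage == stage & rec$genotype == g, ]
      out[, paste(stage, g, sep = "_")] <-
        v$proportion[match(generations, v$generation)]
    }
  }
  out
}

#' Fit index of a scenario against observed trajectories
#'
#' Runs replicate simulations of a scenario and scores each against the
#' observed genotype-proportion trajectories: for every replicate the
#' nRMSE is computed for each of the six variables (AA/AB/BB proportions
#' in eggs and in adults) over generations 1 to G, averaged over
#' variables, then averaged over replicates. Smaller is a better fit.
#'
#' @param observed Either a matrix as produced by
#'   `trajectory_variables()` (rows = generations 1..G, columns
#'   `egg_AA, ..., adult_BB`), or a list of `trajectory` objects whose
#'   per-generation means are taken first (multiple experimental
#'   replicates are pooled by averaging; set `pool = FALSE` to score
#'   against each observed replicate and average the scores).
#' @param cfg,fp,dp,hp Scenario configuration and parameters.
#' @param n_sim_replicates Number of simulation replicates (default 30).
#' @param generations Generations entering the fit (default `1:5`).
#' @param norm Normalization passed to [nrmse()].
#' @param pool Average observed replicates before scoring (default TRUE).
#' @return A `fit_result`: list with `mean_nrmse` (grand mean),
#'   `replicate_nrmse` (per simulated replicate), `by_variable` (mean per
#'   variable), `n_replicates` used and `n_extinct` excluded.
#' @export
fit_index <- function(observed, cfg, fp, dp, hp, n_sim_replicates = 30,
                      generations = 1:5, norm = "mean", pool = TRUE) {
  obs_list <- observed_matrices(observed, generations, pool)
  sims <- run_replicates(cfg, fp, dp, hp, n_sim_replicates)
  extinct <- vapply(sims, function(s)
    s$extinct || max(s$records$generation) < max(generations), logical(1))
  sims <- sims[!extinct]
  if (length(sims) == 0) stop("all simulated replicates went extinct")
  per_rep <- vapply(sims, function(s) {
    sv <- trajectory_variables(s, generations)
    mean(vapply(obs_list, function(ob)
      mean(vapply(colnames(ob), function(v)
        nrmse(ob[, v], sv[, v], norm), numeric(1))), numeric(1)))
  }, numeric(1))
  structure(list(mean_nrmse = mean(per_rep),
                 replicate_nrmse = per_rep,
                 n_replicates = length(sims),
                 n_extinct = sum(extinct)),
            class = "fit_result")
}

observed_matrices <- function(observed, generations, pool) {
  if (is.matrix(observed)) return(list(observed))
  if (inherits(observed, "trajectory")) observed <- list(observed)
  mats <- lapply(observed, trajectory_variables, generations = generations)
  if (pool && length(mats) > 1) {
    list(Reduce(`+`, mats) / length(mats))
  } else mats
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Fit index (mean nRMSE over %d replicates%s): %.4f\n",
              x$n_replicates,
              if (x$n_extinct > 0)
                sprintf(", %d extinct excluded", x$n_extinct) else "",
              x$mean_nrmse))
  invisible(x)
}

#' Grid search over male reproductive success
#'
#' Scores a grid of candidate `T_bb_m` values (relative mating success of
#' beta/beta males; alpha/alpha males have weight 1 and heterozygotes the
#' co-dominant midpoint `(1 + T_bb_m) / 2` unless `T_ab_m` is supplied)
#' against observed trajectories and returns the best-fitting value.
#'
#' @inheritParams fit_index
#' @param grid Candidate `T_bb_m` values in `(0, 1]`.
#' @param T_ab_m Optional function of `T_bb_m` giving the heterozygote
#'   weight (dominance variants); default the co-dominant midpoint.
#' @return A list with `best` (argmin of mean nRMSE), `table` (data frame
#'   `T_bb_m, mean_nrmse, n_extinct`) and `fits` (the `fit_result` per
#'   grid point, named by value).
#' @export
grid_search_male_success <- function(observed, grid, cfg, fp, dp, hp,
                                     n_sim_replicates = 30,
                                     generations = 1:5, norm = "mean",
                                     T_ab_m = NULL) {
  if (length(grid) == 0) stop("empty grid")
  if (any(grid <= 0 | grid > 1)) stop("grid values must lie in (0, 1]")
  mid <- T_ab_m %||% function(t_bb) (1 + t_bb) / 2
  fits <- lapply(seq_along(grid), function(i) {
    t_bb <- grid[i]
    fp_i <- fitness_params(S_f = fp$S["f", ], S_m = fp$S["m", ],
                           T_f = fp$T["f", ],
                           T_m = c(1, mid(t_bb), t_bb),
                           V = fp$V, E = fp$E)
    cfg_i <- cfg
    cfg_i$seed <- derive_seeds(cfg$seed, 10000L + i)
    fit_index(observed, cfg_i, fp_i, dp, hp, n_sim_replicates,
              generations, norm)
  })
  tab <- data.frame(T_bb_m = grid,
                    mean_nrmse = vapply(fits, `[[`, numeric(1), "mean_nrmse"),
                    n_extinct = vapply(fits, `[[`, numeric(1), "n_extinct"))
  list(best = grid[which.min(tab$mean_nrmse)], table = tab,
       fits = stats::setNames(fits, grid))
}

#' Pairwise scenario comparison of fit indices
#'
#' Welch two-sample t-tests on the per-replicate mean nRMSE of each pair
#' of scenarios, with Benjamini-Hochberg adjustment across pairs.
#'
#' @param fits Named list of `fit_result` objects (>= 2).
#' @return Data frame `scenario_a, scenario_b, t, df, p_value, p_adjusted`.
#' @export
compare_scenarios <- function(fits) {
  if (length(fits) < 2) stop("need at least two scenarios")
  nm <- names(fits) %||% as.character(seq_along(fits))
  pairs <- utils::combn(length(fits), 2)
  rows <- apply(pairs, 2, function(ij) {
    a <- fits[[ij[1]]]$replicate_nrmse
    b <- fits[[ij[2]]]$replicate_nrmse
    if (length(a) < 2 || length(b) < 2)
      stop("each scenario needs at least two replicates")
    if (isTRUE(all.equal(a, b))) {
      data.frame(scenario_a = nm[ij[1]], scenario_b = nm[ij[2]],
                 t = 0, df = NA_real_, p_value = 1,
                 stringsAsFactors = FALSE)
    } else {
      tt <- stats::t.test(a, b)
      data.frame(scenario_a = nm[ij[1]], scenario_b = nm[ij[2]],
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out
}
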