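#' Total fitness per sex and genotype, and allele fitnesses
#'
#' Total fitness multiplies the two components: `W[sex, g] = S[sex, g] *
#' T[sex, g]`. Marginal allele fitnesses follow as `w_alpha = W_AA +
#' W_AB / 2` and `w_beta = W_BB + W_AB / 2` per sex, so that
#' `w_alpha + w_beta = W_AA + W_AB + W_BB` exactly.
#'
#' @param fp A [fitness_params()] object (or any list with `S` and `T`
#'   sex-by-genotype matrices).
#' @return A list of class `total_fitness`: matrix `W` (2 x 3) and matrix
#'   `w_allele` (rows `f`/`m`, columns `alpha`/`beta`).
#' @examples
#' total_fitness(lab_fitness())
#' @export
total_fitness <- function(fp) {
  W <- fp$S * fp$T
  w_allele <- cbind(alpha = W[, "AA"] + W[, "AB"] / 2,
                    beta = W[, "BB"] + W[, "AB"] / 2)
  structure(list(W = W, w_allele = w_allele), class = "total_fitness")
}

#' @export
print.total_fitness <- function(x, ...) {
  cat("Total fitness W = S * T:\n"); print(round(x$W, 4))
  cat("Allele fitness:\n"); print(round(x$w_allele, 4))
  od <- classify_overdominance(x)
  cat(sprintf("Overdominance: f = %s, m = %s; sexual antagonism = %s\n",
              od["f"], od["m"], classify_sexual_antagonism(x)))
  invisible(x)
}

#' Classify overdominance in total fitness
#'
#' Per sex, total-fitness overdominance holds when the heterozygote
#' strictly exceeds both homozygotes: `W_AB > W_AA` and `W_AB > W_BB`.
#' Ties do not count.
#'
#' @param tf A `total_fitness` object (or a [fitness_params()], converted
#'   first).
#' @return Named logical vector, one flag per sex.
#' @export
classify_overdominance <- function(tf) {
  tf <- as_total_fitness(tf)
  W <- tf$W
  stats::setNames(W[, "AB"] > W[, "AA"] & W[, "AB"] > W[, "BB"], SEXES)
}

#' Classify sexual antagonism in total fitness
#'
#' Sexual antagonism holds when the two sexes strictly favour different
#' alleles: `w_alpha > w_beta` in one sex and `w_alpha < w_beta` in the
#' other.
#'
#' @inheritParams classify_overdominance
#' @return A single logical.
#' @export
classify_sexual_antagonism <- function(tf) {
  tf <- as_total_fitness(tf)
  d <- tf$w_allele[, "alpha"] - tf$w_allele[, "beta"]
  unname((d["m"] > 0 & d["f"] < 0) | (d["m"] < 0 & d["f"] > 0))
}

as_total_fitness <- function(x) {
  if (inherits(x, "total_fitness")) x else total_fitness(x)
}

#' Classify the fate of a polymorphism from a trajectory
#'
#' @param traj A `trajectory`.
#' @param window Number of final generations over which equilibrium
#'   proportions are averaged (default 20, truncated to the available
#'   generations).
#' @param stage Stage used for the classification (default `"adult"`).
#' @return A list with `status` (`"maintained"`, `"alpha_fixed"`,
#'   `"beta_fixed"` or `"extinct"`), the final-generation `p_final`, and
#'   `equilibrium` mean genotype proportions and `p_equilibrium` over the
#'   window.
#' @export
classify_polymorphism <- function(traj, window = 20, stage = "adult") {
  ps <- p_alpha_series(traj, stage = stage)
  ps <- ps[!is.na(ps$p_alpha), ]
  if (traj$extinct || nrow(ps) == 0) {
    return(list(status = "extinct", p_final = NA_real_,
                equilibrium = stats::setNames(rep(NA_real_, 3), GENOTYPES),
                p_equilibrium = NA_real_))
  }
  p_final <- ps$p_alpha[nrow(ps)]
  status <- if (p_final == 1) "alpha_fixed"
            else if (p_final == 0) "beta_fixed"
            else "maintained"
  gens <- utils::tail(sort(unique(ps$generation)), window)
  pr <- stage_proportions(traj, stage)
  pr <- pr[pr$generation %in% gens, ]
  eq <- vapply(GENOTYPES, function(g)
    mean(pr$proportion[pr$genotype == g], na.rm = TRUE), numeric(1))
  list(status = status, p_final = p_final, equilibrium = eq,
       p_equilibrium = unname(eq["AA"] + eq["AB"] / 2))
}

#' Realized relative survival from a trajectory
#'
#' The adult/egg count ratio per genotype within one sex, averaged over
#' generations and normalized to the BB genotype (value 1 for beta/beta).
#' Under an unlimited habitat this recovers the configured survival
#' ratios; habitat censoring depresses the slow-developing genotypes.
#'
#' @param traj A `trajectory`.
#' @param sex `"m"` or `"f"`.
#' @param generations Generations to average over (default: all with
#'   adults recorded).
#' @return Named numeric vector (AA, AB, BB) with `BB = 1`, or `NA`s when
#'   no BB individuals survived.
#' @export
realized_relative_survival <- function(traj, sex = "m", generations = NULL) {
  r <- traj$records[traj$records$sex == sex, ]
  eggs <- r[r$stage == "egg", ]
  adults <- r[r$stage == "adult", ]
  gens <- generations %||% intersect(unique(eggs$generation),
                                     unique(adults$generation))
  ## per generation: ratio of adult to egg genotype proportions (the egg
  ## record for g >= 1 is the pre-census laid pool; the census is unbiased
  ## in composition, so proportion ratios are comparable), normalized to
  ## BB, then averaged over generations
  per_gen <- lapply(gens, function(g) {
    e <- counts_from_table(eggs[eggs$generation == g, ])
    a <- counts_from_table(adults[adults$generation == g, ])
    if (sum(e) == 0 || sum(a) == 0) return(NULL)
    ratio <- ifelse(e > 0, (a / sum(a)) / (e / sum(e)), NA_real_)
    if (is.na(ratio["BB"]) || ratio["BB"] == 0) return(NULL)
    ratio / ratio["BB"]
  })
  per_gen <- per_gen[!vapply(per_gen, is.null, logical(1))]
  if (length(per_gen) == 0)
    return(stats::setNames(rep(NA_real_, 3), GENOTYPES))
  colMeans(do.call(rbind, per_gen), na.rm = TRUE)
}

#' Parameter-space sweep
#'
#' Runs replicate simulations over a grid of parameter points and
#' summarizes, per point, the fraction of replicates maintaining the
#' polymorphism, the mean equilibrium alpha frequency and genotype
#' proportions, the extinction tally, and the balancing-selection
#' mechanism flags (from the configured `S * T`, and optionally from the
#' realized survival of the final replicate trajectories).
#'
#' @param grid A data frame, one row per parameter point. Recognized
#'   columns: `T_bb_m` (beta/beta male success; heterozygote at the
#'   co-dominant midpoint), `A_mean`, `A_var`, plus the theoretical-space
#'   columns `s_m`, `s_f`, `t_m`, `t_f`, `H_s`, `H_t` (when present the
#'   fitness block is rebuilt via [from_theoretical()]). Unrecognized
#'   columns are carried through to the output.
#' @param cfg Base [sim_config()]; per-point, per-replicate seeds derive
#'   from `cfg$seed`, the grid row and the replicate index.
#' @param fp,dp,hp Base parameters, overridden per point.
#' @param n_replicates Replicates per grid point.
#' @param window Equilibrium averaging window (see
#'   [classify_polymorphism()]).
#' @param realized Also compute realized-survival mechanism flags
#'   (slower; default FALSE).
#' @return A list with `summary` (one row per grid point) and `replicates`
#'   (one row per point x replicate: status, final and equilibrium p).
#' @export
sweep_outcomes <- function(grid, cfg, fp, dp, hp, n_replicates = 10,
                           window = 20, realized = FALSE) {
  stopifnot(is.data.frame(grid), nrow(grid) > 0)
  sum_rows <- vector("list", nrow(grid))
  rep_rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, , drop = FALSE]
    fp_i <- fp; hp_i <- hp
    if (all(c("s_m", "s_f", "t_m", "t_f", "H_s", "H_t") %in% names(g))) {
      fp_i <- from_theoretical(theoretical_params(
        s_m = g$s_m, s_f = g$s_f, t_m = g$t_m, t_f = g$t_f,
        H_s = g$H_s, H_t = g$H_t), V = fp$V, E = fp$E)
    }
    if (!is.null(g$T_bb_m)) {
      fp_i <- fitness_params(S_f = fp_i$S["f", ], S_m = fp_i$S["m", ],
                             T_f = fp_i$T["f", ],
                             T_m = c(1, (1 + g$T_bb_m) / 2, g$T_bb_m),
                             V = fp_i$V, E = fp_i$E)
    }
    if (!is.null(g$A_mean) || !is.null(g$A_var)) {
      hp_i <- habitat_params(A_mean = g$A_mean %||% hp$A_mean,
                             A_var = g$A_var %||% hp$A_var)
    }
    seeds <- derive_seeds(cfg$seed, i * 100000L + seq_len(n_replicates))
    cls <- lapply(seq_len(n_replicates), function(r) {
      tr <- run_simulation(cfg, fp_i, dp, hp_i, seed = seeds[r])
      cl <- classify_polymorphism(tr, window = window)
      if (realized) cl$realized_surv_m <- realized_relative_survival(tr, "m")
      cl
    })
    status <- vapply(cls, `[[`, character(1), "status")
    rep_rows[[i]] <- data.frame(
      point = i, replicate = seq_len(n_replicates), status = status,
      p_final = vapply(cls, `[[`, numeric(1), "p_final"),
      p_equilibrium = vapply(cls, `[[`, numeric(1), "p_equilibrium"),
      stringsAsFactors = FALSE)
    tf <- total_fitness(fp_i)
    od <- classify_overdominance(tf)
    srow <- data.frame(
      point = i,
      frac_polymorphic = mean(status == "maintained"),
      frac_alpha_fixed = mean(status == "alpha_fixed"),
      frac_beta_fixed = mean(status == "beta_fixed"),
      frac_extinct = mean(status == "extinct"),
      mean_p_eq = mean(vapply(cls, `[[`, numeric(1), "p_equilibrium"),
                       na.rm = TRUE),
      overdominance_f = unname(od["f"]),
      overdominance_m = unname(od["m"]),
      sexual_antagonism = classify_sexual_antagonism(tf),
      stringsAsFactors = FALSE)
    if (realized) {
      rs <- vapply(cls, function(cl) cl$realized_surv_m, numeric(3))
      srow$realized_S_AA_m <- mean(rs["AA", ], na.rm = TRUE)
      srow$realized_S_AB_m <- mean(rs["AB", ], na.rm = TRUE)
    }
    sum_rows[[i]] <- cbind(g, srow, row.names = NULL)
  }
  list(summary = do.call(rbind, sum_rows),
       replicates = do.call(rbind, rep_rows))
}
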