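## Individuals are stored column-wise for speed: genotype and sex as integer
## codes (genotype 1/2/3 = AA/AB/BB; sex 1/2 = f/m), development time as a
## numeric vector once assigned at the larval stage.

new_cohort <- function(genotype, sex, dev_time = NULL) {
  structure(list(genotype = as.integer(genotype), sex = as.integer(sex),
                 dev_time = dev_time),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Cohort of %d individuals\n", length(x$genotype)))
  print(cohort_counts(x))
  invisible(x)
}

#' Cohort size and composition
#'
#' @param cohort A cohort as produced by [initialize_cohort()] or the
#'   life-cycle steps.
#' @return `cohort_size()` the number of individuals; `cohort_counts()` a
#'   2 x 3 matrix of counts (rows `f`/`m`, columns `AA`/`AB`/`BB`).
#' @export
cohort_size <- function(cohort) length(cohort$genotype)

#' @rdname cohort_size
#' @export
cohort_counts <- function(cohort) {
  m <- matrix(0L, 2, 3, dimnames = list(SEXES, GENOTYPES))
  if (cohort_size(cohort) > 0) {
    tab <- table(factor(cohort$sex, levels = 1:2),
                 factor(cohort$genotype, levels = 1:3))
    m[] <- as.integer(tab)
  }
  m
}

#' Draw the founding egg cohort
#'
#' `K` eggs with genotypes drawn multinomially from the configured initial
#' proportions (Hardy-Weinberg at `p0` by default) and sex drawn
#' independently with probability `sex_ratio` of being female.
#'
#' @param cfg A [sim_config()].
#' @return An egg cohort.
#' @export
initialize_cohort <- function(cfg) {
  geno <- sample.int(3L, cfg$K, replace = TRUE, prob = cfg$initial_props)
  sex <- ifelse(stats::runif(cfg$K) < cfg$sex_ratio, 1L, 2L)
  new_cohort(geno, sex)
}

#' Viability selection on eggs
#'
#' Each egg survives the growth phase independently with probability
#' `V * S[sex, genotype]` — the product of global viability and the
#' sex-by-genotype relative survival weight.
#'
#' @param eggs An egg cohort.
#' @param fp A [fitness_params()] object.
#' @return The cohort of surviving larvae.
#' @export
survive_viability <- function(eggs, fp) {
  n <- cohort_size(eggs)
  if (n == 0) return(eggs)
  p_surv <- fp$V * fp$S[cbind(eggs$sex, eggs$genotype)]
  keep <- stats::runif(n) < p_surv
  new_cohort(eggs$genotype[keep], eggs$sex[keep])
}

#' Individual development time
#'
#' A larva's development time is the cube root of the product of three
#' independent draws from `U[mu * (1 - c), mu * (1 + c)]`, where `mu` is
#' the sex-by-genotype mean. The geometric averaging concentrates the
#' distribution around (slightly below) `mu`: the expectation is
#' `mu * (0.75 * ((1 + c)^(4/3) - (1 - c)^(4/3)) / (2 * c))^3`, about
#' `0.971 * mu` at `c = 0.5`, and the support is
#' `[mu * (1 - c), mu * (1 + c)]`.
#'
#' @param sex,genotype Vectors of codes (`"f"`/`"m"` or 1/2;
#'   `"AA"`/`"AB"`/`"BB"` or 1/2/3), recycled to a common length.
#' @param dp A [development_params()] object.
#' @return Numeric vector of development times (days).
#' @export
draw_development_time <- function(sex, genotype, dp) {
  sex <- sex_code(sex); genotype <- geno_code(genotype)
  n <- max(length(sex), length(genotype))
  sex <- rep_len(sex, n); genotype <- rep_len(genotype, n)
  mu <- dp$mu[cbind(sex, genotype)]
  lo <- mu * (1 - dp$c); hi <- mu * (1 + dp$c)
  u1 <- stats::runif(n, lo, hi)
  u2 <- stats::runif(n, lo, hi)
  u3 <- stats::runif(n, lo, hi)
  (u1 * u2 * u3)^(1 / 3)
}

sex_code <- function(sex) {
  if (is.character(sex)) match(sex, SEXES) else as.integer(sex)
}
geno_code <- function(genotype) {
  if (is.character(genotype)) match(genotype, GENOTYPES) else as.integer(genotype)
}

#' Individual habitat availability
#'
#' Each larva draws the number of days its wrackbed patch persists from
#' `U[A_mean - A_var, A_mean + A_var]`.
#'
#' @param n Number of draws.
#' @param hp A [habitat_params()] object.
#' @return Numeric vector of availabilities (days).
#' @export
draw_habitat_availability <- function(n, hp) {
  if (hp$A_var == 0) rep(hp$A_mean, n)
  else stats::runif(n, hp$A_mean - hp$A_var, hp$A_mean + hp$A_var)
}

#' Maturation: development versus habitat loss
#'
#' Assigns each larva a development time (if not already present) and a
#' habitat availability, and keeps exactly the larvae whose development
#' time is shorter than their availability.
#'
#' @param larvae A larval cohort.
#' @param dp,hp Development and habitat parameters.
#' @return The adult cohort.
#' @export
mature <- function(larvae, dp, hp) {
  n <- cohort_size(larvae)
  if (n == 0) return(larvae)
  d <- larvae$dev_time
  if (is.null(d)) d <- draw_development_time(larvae$sex, larvae$genotype, dp)
  a <- draw_habitat_availability(n, hp)
  keep <- d < a
  new_cohort(larvae$genotype[keep], larvae$sex[keep])
}

#' Exact maturation probability
#'
#' The probability that a larva of a given sex and genotype matures,
#' `P(D < A)`, computed by numerical integration of the development-time
#' distribution (cube root of a product of three uniforms) against the
#' uniform habitat-availability distribution. Used by the deterministic
#' recursion oracle and for analysis of habitat censoring.
#'
#' @param mu Mean development time (days).
#' @param c Variation coefficient.
#' @param hp A [habitat_params()] object.
#' @return A probability.
#' @export
maturation_prob <- function(mu, c, hp) {
  lo <- mu * (1 - c); hi <- mu * (1 + c)
  a1 <- hp$A_mean - hp$A_var; a2 <- hp$A_mean + hp$A_var
  if (c == 0) {
    ## development time is exactly mu
    if (hp$A_var == 0) return(as.numeric(mu < a1))
    return(min(max((a2 - mu) / (a2 - a1), 0), 1))
  }
  ## F_D(x) = P(u1*u2*u3 < x^3) for iid u ~ U[lo, hi]: marginalize u3 in
  ## closed form and integrate the clamped cdf over the (u1, u2) square by
  ## composite Simpson (the integrand is piecewise smooth; a fine fixed
  ## grid is robust where adaptive quadrature stalls on the kinks)
  n_u <- 201L
  u <- seq(lo, hi, length.out = n_u)
  w_u <- simpson_weights(n_u) * (hi - lo) / (n_u - 1L)
  G <- outer(u, u)
  F_D <- function(x) {
    vapply(x, function(xi) {
      if (xi <= lo) return(0)
      if (xi >= hi) return(1)
      inner <- pmin(pmax((xi^3 / G - lo) / (hi - lo), 0), 1)
      drop(t(w_u) %*% inner %*% w_u) / (hi - lo)^2
    }, numeric(1))
  }
  if (hp$A_var == 0) return(F_D(a1))
  n_a <- 41L
  av <- seq(a1, a2, length.out = n_a)
  w_a <- simpson_weights(n_a) * (a2 - a1) / (n_a - 1L)
  sum(w_a * F_D(av)) / (a2 - a1)
}

## composite Simpson weight pattern (1, 4, 2, ..., 4, 1) / 3 for odd n
simpson_weights <- function(n) {
  w <- rep(c(2, 4), length.out = n)
  w[1] <- 1; w[n] <- 1
  w / 3
}

## Effective male mating weights, optionally with negative frequency
## dependence: weight[g] = T_m[g] * (1 - d * f_m[g]), floored at 0.
male_weights <- function(male_counts, fp, freq_dep = 0) {
  w <- fp$T["m", ]
  if (freq_dep > 0) {
    f_m <- male_counts / sum(male_counts)
    w <- pmax(w * (1 - freq_dep * f_m), 0)
  }
  male_counts * w
}

#' Reproduction: fecundity, mate choice and Mendelian inheritance
#'
#' Every adult female mates and lays `round(E * T_f[genotype])` eggs. For
#' each female one father is drawn (independently across females, with
#' replacement — males can mate repeatedly) with probability proportional
#' to `N_m[g] * T_m[g]`, i.e. male genotype counts weighted by relative
#' mating success, optionally modulated by negative frequency dependence
#' (see [sim_config()]). Each egg receives one uniformly chosen allele
#' from each parent and a sex drawn with probability `sex_ratio` of being
#' female.
#'
#' @param adults The adult cohort.
#' @param fp A [fitness_params()] object.
#' @param sex_ratio Probability an egg is female.
#' @param freq_dep Frequency-dependence coefficient (default 0).
#' @return The uncensused egg cohort of the next generation, or `NULL` if
#'   an adult sex is missing or no eggs are produced (extinction).
#' @export
reproduce <- function(adults, fp, sex_ratio = 0.5, freq_dep = 0) {
  counts <- cohort_counts(adults)
  if (sum(counts["f", ]) == 0 || sum(counts["m", ]) == 0) return(NULL)
  females <- adults$genotype[adults$sex == 1L]
  eggs_per_female <- round(fp$E * fp$T["f", females])
  total <- sum(eggs_per_female)
  if (total == 0) return(NULL)
  w <- male_weights(counts["m", ], fp, freq_dep)
  if (sum(w) == 0) return(NULL)
  fathers <- sample.int(3L, length(females), replace = TRUE, prob = w)
  mother_g <- rep.int(females, eggs_per_female)
  father_g <- rep.int(fathers, eggs_per_female)
  a_m <- gamete_alpha(mother_g)
  a_f <- gamete_alpha(father_g)
  geno <- 3L - (a_m + a_f)          # 2 alpha alleles -> AA, 0 -> BB
  sex <- ifelse(stats::runif(total) < sex_ratio, 1L, 2L)
  new_cohort(geno, sex)
}

## One gamete per parent: 1 if it carries alpha. AA always, BB never,
## AB a fair coin.
gamete_alpha <- function(parent_genotype) {
  a <- as.integer(parent_genotype == 1L)
  het <- parent_genotype == 2L
  if (any(het)) a[het] <- as.integer(stats::runif(sum(het)) < 0.5)
  a
}

#' Census to carrying capacity
#'
#' A uniform subsample without replacement of `min(K, n)` eggs initiates
#' the next generation, mirroring the egg census of the experiment or a
#' limited carrying capacity in the wild.
#'
#' @param eggs The uncensused egg cohort.
#' @param K Carrying capacity.
#' @return The censused cohort, or `NULL` when no eggs remain.
#' @export
census <- function(eggs, K) {
  n <- cohort_size(eggs)
  if (n == 0) return(NULL)
  if (n <= K) return(eggs)
  keep <- sample.int(n, K)
  new_cohort(eggs$genotype[keep], eggs$sex[keep])
}

record_stage <- function(cohort, generation, stage) {
  counts <- cohort_counts(cohort)
  data.frame(generation = generation,
             stage = stage,
             sex = rep(SEXES, times = 3),
             genotype = rep(GENOTYPES, each = 2),
             count = as.integer(counts[cbind(rep(1:2, 3),
                                             rep(1:3, each = 2))]),
             stringsAsFactors = FALSE)
}

#' Run one replicate of the individual-based life cycle
#'
#' Iterates the two-phase generation cycle: growth (viability selection,
#' development, habitat censoring) producing the adults of the current
#' generation, then reproduction (fecundity, weighted mate choice,
#' Mendelian inheritance) producing the eggs of the next generation,
#' which are censused down to `K`. Egg and adult genotype-by-sex counts
#' are recorded at every generation; eggs are recorded before the census.
#'
#' Generation 0 is the founding egg cohort and the adults that emerge from
#' it; each reproduction step increments the generation, so a run with
#' `n_generations = 5` records eggs and adults for generations 0 through 5.
#'
#' If a generation ends with no adults of one sex, or no eggs, the
#' replicate is marked extinct and the trajectory truncated.
#'
#' @param cfg A [sim_config()]; its `seed` is used unless `seed` is given.
#' @param fp,dp,hp Fitness, development and habitat parameters.
#' @param seed Optional integer overriding `cfg$seed`.
#' @return A `trajectory` object: list with `records` (long data frame
#'   `generation, stage, sex, genotype, count`), `extinct` flag, `seed`
#'   and a config echo.
#' @examples
#' p <- lab_params()
#' cfg <- sim_config(K = 500, n_generations = 3, p0 = 0.32, seed = 42)
#' tr <- run_simulation(cfg, p$fitness, p$development, p$habitat)
#' p_alpha_series(tr, stage = "adult")
#' @export
run_simulation <- function(cfg, fp, dp, hp, seed = NULL) {
  seed <- seed %||% cfg$seed
  set.seed(seed)
  recs <- vector("list", 2L * (cfg$n_generations + 1L))
  ri <- 0L
  add <- function(cohort, gen, stage) {
    ri <<- ri + 1L
    recs[[ri]] <<- record_stage(cohort, gen, stage)
  }
  extinct <- FALSE
  eggs <- initialize_cohort(cfg)
  add(eggs, 0L, "egg")
  for (gen in 0:cfg$n_generations) {
    larvae <- survive_viability(eggs, fp)
    adults <- mature(larvae, dp, hp)
    add(adults, gen, "adult")
    counts <- cohort_counts(adults)
    if (sum(counts["f", ]) == 0 || sum(counts["m", ]) == 0) {
      extinct <- TRUE
      break
    }
    if (gen == cfg$n_generations) break
    next_eggs <- reproduce(adults, fp, cfg$sex_ratio, cfg$freq_dep)
    if (is.null(next_eggs)) {
      extinct <- TRUE
      break
    }
    add(next_eggs, gen + 1L, "egg")
    eggs <- census(next_eggs, cfg$K)
    if (is.null(eggs)) {
      extinct <- TRUE
      break
    }
  }
  structure(list(records = do.call(rbind, recs[seq_len(ri)]),
                 extinct = extinct, seed = seed, config = cfg),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  gmax <- max(x$records$generation)
  cat(sprintf("Trajectory: %d generations recorded (seed %d)%s\n",
              gmax, x$seed, if (x$extinct) " [EXTINCT]" else ""))
  p <- p_alpha_series(x, stage = "adult")
  if (nrow(p) > 0) {
    cat("Adult alpha frequency by generation:\n")
    print(round(stats::setNames(p$p_alpha, p$generation), 3))
  }
  invisible(x)
}

#' Run replicate simulations with derived seeds
#'
#' Runs `n_replicates` independent replicates; replicate `i` uses the seed
#' `(seed * 1000003 + i * 7919) mod 2^31 - 1`, so a whole batch is
#' reproducible from the single master seed.
#'
#' @inheritParams run_simulation
#' @param n_replicates Number of replicates (default from `cfg`).
#' @return A list of `trajectory` objects.
#' @export
run_replicates <- function(cfg, fp, dp, hp, n_replicates = NULL) {
  n_replicates <- n_replicates %||% cfg$n_replicates
  seeds <- derive_seeds(cfg$seed, seq_len(n_replicates))
  lapply(seq_len(n_replicates), function(i)
    run_simulation(cfg, fp, dp, hp, seed = seeds[i]))
}

## Child-seed derivation: a fixed affine mix of the master seed and an
## index, reduced mod 2^31 - 1 so seeds stay valid 32-bit integers.
derive_seeds <- function(master, index) {
  as.integer((as.numeric(master) * 1000003 + as.numeric(index) * 7919) %%
               2147483647)
}

#' Stage proportions and allele-frequency series from a trajectory
#'
#' `stage_proportions()` returns genotype proportions per generation for a
#' stage, pooled over sex by default; `p_alpha_series()` the alpha allele
#' frequency per generation.
#'
#' @param traj A `trajectory`.
#' @param stage `"egg"` or `"adult"`.
#' @param sex `"all"` (pool sexes), `"f"` or `"m"`.
#' @return A data frame keyed by generation.
#' @export
stage_proportions <- function(traj, stage = c("adult", "egg"), sex = "all") {
  stage <- match.arg(stage)
  r <- traj$records[traj$records$stage == stage, ]
  if (sex != "all") r <- r[r$sex == sex, ]
  agg <- stats::aggregate(count ~ generation + genotype, data = r, FUN = sum)
  tot <- stats::aggregate(count ~ generation, data = agg, FUN = sum)
  names(tot)[2] <- "total"
  out <- merge(agg, tot, by = "generation")
  out$proportion <- ifelse(out$total > 0, out$count / out$total, NA_real_)
  out[order(out$generation, match(out$genotype, GENOTYPES)),
      c("generation", "genotype", "count", "proportion")]
}

#' @rdname stage_proportions
#' @export
p_alpha_series <- function(traj, stage = c("adult", "egg"), sex = "all") {
  stage <- match.arg(stage)
  pr <- stage_proportions(traj, stage, sex)
  sp <- split(pr, pr$generation)
  data.frame(
    generation = as.integer(names(sp)),
    p_alpha = vapply(sp, function(d) {
      n <- stats::setNames(d$count, d$genotype)
      if (sum(n) == 0) return(NA_real_)
      allele_frequency(n)
    }, numeric(1)),
    row.names = NULL)
}

#' Deterministic infinite-population recursion
#'
#' The expected-value counterpart of [run_simulation()], used as a
#' verification oracle and for fast qualitative analysis. Each generation:
#' the expected adult composition applies effective survival
#' `V * S[sex, g] * P(D < A)` (maturation probability by numerical
#' integration) to the egg genotype proportions; the maternal alpha-gamete
#' frequency weights female genotype frequencies by `T_f` and the paternal
#' one weights male frequencies by `T_m`; the next egg genotype
#' proportions are the Hardy-Weinberg-style products of the two gamete
#' frequencies.
#'
#' @param fp,dp,hp Parameter objects.
#' @param initial_props Initial egg genotype proportions (AA, AB, BB).
#' @param n_generations Number of reproduction cycles.
#' @param freq_dep Frequency-dependence coefficient on male success.
#' @return A data frame with one row per generation x stage: genotype
#'   proportions (pooled over sex for eggs; adult rows give the pooled and
#'   per-sex values) and alpha frequency.
#' @export
deterministic_recursion <- function(fp, dp, hp, initial_props,
                                    n_generations, freq_dep = 0) {
  props <- named_geno(initial_props)
  props <- props / sum(props)
  q <- matrix(0, 2, 3, dimnames = list(SEXES, GENOTYPES))
  for (s in 1:2) for (g in 1:3)
    q[s, g] <- maturation_prob(dp$mu[s, g], dp$c, hp)
  eff_surv <- fp$V * fp$S * q           # per sex x genotype
  out <- vector("list", 2L * (n_generations + 1L))
  oi <- 0L
  emit <- function(gen, stage, pooled, f = NULL, m = NULL) {
    oi <<- oi + 1L
    out[[oi]] <<- data.frame(
      generation = gen, stage = stage,
      genotype = GENOTYPES, proportion = unname(pooled),
      prop_f = if (is.null(f)) NA_real_ else unname(f),
      prop_m = if (is.null(m)) NA_real_ else unname(m),
      p_alpha = unname(pooled[1] + pooled[2] / 2),
      stringsAsFactors = FALSE)
  }
  for (gen in 0:n_generations) {
    emit(gen, "egg", props)
    ## adults: each egg is female w.p. 1/2; survival differs by sex
    w_f <- props * eff_surv["f", ]
    w_m <- props * eff_surv["m", ]
    if (sum(w_f) == 0 || sum(w_m) == 0) break
    f_f <- w_f / sum(w_f)
    f_m <- w_m / sum(w_m)
    pooled <- (w_f + w_m) / sum(w_f + w_m)
    emit(gen, "adult", pooled, f_f, f_m)
    if (gen == n_generations) break
    tw_m <- fp$T["m", ]
    if (freq_dep > 0) tw_m <- pmax(tw_m * (1 - freq_dep * f_m), 0)
    wf <- f_f * fp$T["f", ]
    wm <- f_m * tw_m
    if (sum(wf) == 0 || sum(wm) == 0) break
    gam_f <- sum(wf * c(1, 0.5, 0)) / sum(wf)   # maternal alpha gamete
    gam_m <- sum(wm * c(1, 0.5, 0)) / sum(wm)   # paternal alpha gamete
    props <- c(AA = gam_f * gam_m,
               AB = gam_f * (1 - gam_m) + (1 - gam_f) * gam_m,
               BB = (1 - gam_f) * (1 - gam_m))
  }
  do.call(rbind, out[seq_len(oi)])
}
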