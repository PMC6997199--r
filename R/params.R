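#' @keywords internal
"_PACKAGE"

## Canonical genotype and sex codes used throughout the package.
## AA = alpha/alpha, AB = alpha/beta heterozygote, BB = beta/beta.
GENOTYPES <- c("AA", "AB", "BB")
SEXES <- c("f", "m")

`%||%` <- function(a, b) if (is.null(a)) b else a

named_geno <- function(x) {
  x <- as.numeric(x)
  if (length(x) != 3L) stop("expected one value per genotype (AA, AB, BB)")
  stats::setNames(x, GENOTYPES)
}

#' Sex- and genotype-specific fitness parameters
#'
#' Bundles the four fitness components of the life cycle: relative
#' egg-to-adult survival `S` and relative reproductive success `T`, each per
#' sex and inversion genotype, plus the global egg-to-adult viability `V`
#' and the baseline fecundity `E` (eggs laid per female, before the
#' genotype-specific factor `T_f`).
#'
#' `S` and `T` are dimensionless weights on a per-sex scale: within a sex
#' the best genotype conventionally has weight 1. An egg survives the
#' growth phase with probability `V * S[sex, genotype]`; a female of
#' genotype g lays `round(E * T_f[g])` eggs; a male of genotype g is drawn
#' as a mate with probability proportional to `N_m[g] * T_m[g]`.
#'
#' @param S_f,S_m Relative survival for females/males, length-3 numeric in
#'   genotype order AA, AB, BB, each in `[0, 1]`.
#' @param T_f,T_m Relative reproductive success, same shape and range.
#' @param V Global egg-to-adult survival probability in `(0, 1]`.
#' @param E Baseline eggs per female (positive integer).
#' @return An object of class `fitness_params`: a list with matrices `S` and
#'   `T` (rows `f`/`m`, columns `AA`/`AB`/`BB`) and scalars `V`, `E`.
#' @examples
#' fp <- lab_fitness()
#' fp$S["f", "BB"]   # best-surviving female genotype
#' @export
fitness_params <- function(S_f, S_m, T_f, T_m, V = 0.3, E = 70) {
  S <- rbind(f = named_geno(S_f), m = named_geno(S_m))
  Tm <- rbind(f = named_geno(T_f), m = named_geno(T_m))
  if (any(S < 0 | S > 1)) stop("relative survival S must lie in [0, 1]")
  if (any(Tm < 0 | Tm > 1)) stop("relative reproductive success T must lie in [0, 1]")
  if (!is.numeric(V) || length(V) != 1L || V <= 0 || V > 1)
    stop("global viability V must be a probability in (0, 1]")
  if (!is.numeric(E) || length(E) != 1L || E <= 0 || E != round(E))
    stop("baseline fecundity E must be a positive integer")
  structure(list(S = S, T = Tm, V = V, E = as.integer(E)),
            class = "fitness_params")
}

#' @export
print.fitness_params <- function(x, ...) {
  cat("Fitness parameters (rows: sex, cols: genotype)\n")
  cat("Relative survival S:\n"); print(x$S)
  cat("Relative reproductive success T:\n"); print(x$T)
  cat(sprintf("Global viability V = %g, baseline fecundity E = %d eggs\n",
              x$V, x$E))
  invisible(x)
}

#' Development-time parameters
#'
#' Mean larval development times per sex and genotype (days) and the
#' variation coefficient `c` of the individual development-time draw: each
#' individual's time is the cube root of the product of three independent
#' uniforms on `[mu * (1 - c), mu * (1 + c)]`.
#'
#' @param mu_f,mu_m Mean development times (days), length-3 in genotype
#'   order AA, AB, BB.
#' @param c Variation coefficient, `0 <= c < 1`.
#' @return An object of class `development_params` with matrix `mu` and
#'   scalar `c`.
#' @export
development_params <- function(mu_f, mu_m, c = 0.5) {
  mu <- rbind(f = named_geno(mu_f), m = named_geno(mu_m))
  if (any(mu <= 0)) stop("mean development times must be positive")
  if (!is.numeric(c) || length(c) != 1L || c < 0 || c >= 1)
    stop("variation coefficient c must satisfy 0 <= c < 1")
  structure(list(mu = mu, c = c), class = "development_params")
}

#' @export
print.development_params <- function(x, ...) {
  cat("Development-time means (days):\n"); print(x$mu)
  cat(sprintf("Variation coefficient c = %g\n", x$c))
  invisible(x)
}

#' Habitat-availability parameters
#'
#' The larval habitat (the wrackbed) persists for a uniformly distributed
#' number of days: each larva draws its own availability
#' `A_i ~ U[A_mean - A_var, A_mean + A_var]` and matures only if its
#' development time is shorter than `A_i`. `A_var` is the half-width of the
#' uniform; `A_var = 0` makes habitat duration deterministic.
#'
#' @param A_mean Mean habitat duration (days), positive.
#' @param A_var Half-width of the duration distribution (days),
#'   non-negative, with `A_mean - A_var >= 0`.
#' @return An object of class `habitat_params`.
#' @export
habitat_params <- function(A_mean, A_var = 2) {
  if (!is.numeric(A_mean) || length(A_mean) != 1L || A_mean <= 0)
    stop("A_mean must be a positive number of days")
  if (!is.numeric(A_var) || length(A_var) != 1L || A_var < 0)
    stop("A_var must be non-negative")
  if (A_mean - A_var < 0)
    stop("A_mean - A_var must be non-negative")
  structure(list(A_mean = A_mean, A_var = A_var), class = "habitat_params")
}

#' @export
print.habitat_params <- function(x, ...) {
  cat(sprintf("Habitat availability: U[%g, %g] days (A_mean = %g, A_var = %g)\n",
              x$A_mean - x$A_var, x$A_mean + x$A_var, x$A_mean, x$A_var))
  invisible(x)
}

#' Laboratory-fitted default parameters
#'
#' The empirical parameter set fitted from the five-generation laboratory
#' evolution experiment: sex-specific relative survival and reproductive
#' success per genotype, global viability 0.3, fecundity 70 eggs, the
#' measured development-time means, and an effectively unlimited habitat
#' (30 +/- 2 days, far beyond the slowest male development time).
#'
#' The male reproductive-success weights (1, 0.55, 0.1) are the best-fit
#' values from the trajectory-fitting analysis: a 10-fold mating advantage
#' of alpha/alpha over beta/beta males with a co-dominant heterozygote.
#'
#' @return `lab_fitness()`, `lab_development()` and `lab_habitat()` return
#'   the individual parameter objects; `lab_params()` returns all three as
#'   a named list `list(fitness, development, habitat)`.
#' @examples
#' lab_params()
#' @export
lab_fitness <- function() {
  fitness_params(S_f = c(0.71, 0.90, 1.0),
                 S_m = c(0.81, 1.0, 0.88),
                 T_f = c(1.0, 0.97, 0.87),
                 T_m = c(1.0, 0.55, 0.1),
                 V = 0.3, E = 70)
}

#' @rdname lab_fitness
#' @export
lab_development <- function() {
  development_params(mu_f = c(9.0, 8.7, 9.0),
                     mu_m = c(12.8, 10.3, 8.8),
                     c = 0.5)
}

#' @rdname lab_fitness
#' @export
lab_habitat <- function() habitat_params(A_mean = 30, A_var = 2)

#' @rdname lab_fitness
#' @export
lab_params <- function() {
  list(fitness = lab_fitness(),
       development = lab_development(),
       habitat = lab_habitat())
}

#' Theoretical selection/dominance parameterization
#'
#' The abstract parameterization of the trade-off: sex-specific selection
#' coefficients on survival (`s_m`, `s_f`) and reproduction (`t_m`, `t_f`)
#' and dominance coefficients shared between the sexes for survival (`H_s`)
#' and reproduction (`H_t`). Survival selection acts against the alpha
#' allele and reproductive selection against beta, so the two components
#' pull in opposite directions — the antagonistic pleiotropy at the heart
#' of the model.
#'
#' @param s_m,s_f,t_m,t_f,H_s,H_t Numbers in `[0, 1]`.
#' @return An object of class `theoretical_params`.
#' @seealso [from_theoretical()] to expand into [fitness_params()].
#' @export
theoretical_params <- function(s_m, s_f, t_m, t_f, H_s, H_t) {
  vals <- c(s_m = s_m, s_f = s_f, t_m = t_m, t_f = t_f, H_s = H_s, H_t = H_t)
  if (!is.numeric(vals) || length(vals) != 6L || anyNA(vals))
    stop("all six theoretical parameters are required")
  if (any(vals < 0 | vals > 1))
    stop("theoretical parameters must lie in [0, 1]")
  structure(as.list(vals), class = "theoretical_params")
}

#' Expand theoretical parameters into fitness parameters
#'
#' Builds the sex-by-genotype fitness table from selection and dominance
#' coefficients: survival `S = (1 - s, 1 - s * H_s, 1)` and reproduction
#' `T = (1, 1 - t * H_t, 1 - t)` for genotypes (AA, AB, BB) in each sex.
#' With `t_m = 0.9`, `H_t = 0.5` this reproduces the laboratory male
#' mating-success weights (1, 0.55, 0.1).
#'
#' @param tp A [theoretical_params()] object.
#' @param V,E Global viability and fecundity, passed through.
#' @return A [fitness_params()] object.
#' @export
from_theoretical <- function(tp, V = 0.3, E = 70) {
  stopifnot(inherits(tp, "theoretical_params"))
  fitness_params(
    S_f = c(1 - tp$s_f, 1 - tp$s_f * tp$H_s, 1),
    S_m = c(1 - tp$s_m, 1 - tp$s_m * tp$H_s, 1),
    T_f = c(1, 1 - tp$t_f * tp$H_t, 1 - tp$t_f),
    T_m = c(1, 1 - tp$t_m * tp$H_t, 1 - tp$t_m),
    V = V, E = E)
}

#' Density-dependent survival presets
#'
#' Larval density modulates relative egg-to-adult survival. The `"low"`
#' preset is the laboratory-fitted survival block (the experiment ran at
#' low density). Medium- and high-density survival values come from other
#' laboratory studies and are not hard-coded here: supply them via
#' `table`, a list with elements `S_f` and `S_m` (length-3, genotype order
#' AA, AB, BB). A medium-density table is expected to encode survival
#' overdominance (heterozygote maximal) in both sexes, and is validated
#' accordingly.
#'
#' @param name One of `"low"`, `"medium"`, `"high"`.
#' @param table For `"medium"`/`"high"`: list with `S_f`, `S_m`.
#' @param base Fitness parameters whose reproduction block is retained
#'   (default [lab_fitness()]).
#' @return A [fitness_params()] object with the preset survival block.
#' @export
density_preset <- function(name, table = NULL, base = lab_fitness()) {
  name <- match.arg(name, c("low", "medium", "high"))
  if (name == "low") return(base)
  if (is.null(table) || is.null(table$S_f) || is.null(table$S_m))
    stop(sprintf("density preset '%s' requires a user table with S_f and S_m",
                 name))
  fp <- fitness_params(S_f = table$S_f, S_m = table$S_m,
                       T_f = base$T["f", ], T_m = base$T["m", ],
                       V = base$V, E = base$E)
  if (name == "medium" &&
      !(which.max(fp$S["f", ]) == 2L && which.max(fp$S["m", ]) == 2L))
    stop("medium-density survival must be overdominant (AB maximal) in both sexes")
  fp
}

#' Simulation configuration
#'
#' @param K Egg carrying capacity: the number of eggs that initiates each
#'   generation (the census size).
#' @param n_generations Number of reproduction cycles to simulate; the
#'   trajectory records generations `0..n_generations`.
#' @param p0 Initial alpha allele frequency; the initial egg cohort is drawn
#'   from Hardy-Weinberg proportions at `p0`. Ignored if `initial_props`
#'   is given.
#' @param initial_props Explicit initial genotype proportions (AA, AB, BB),
#'   summing to 1.
#' @param sex_ratio Probability that an egg is female (default 0.5).
#' @param n_replicates Default number of replicate runs.
#' @param seed Integer master seed; all randomness derives from it.
#' @param freq_dep Negative frequency-dependence coefficient `d >= 0` on
#'   male mating success: the effective male weight is
#'   `T_m[g] * (1 - d * f_m[g])` with `f_m[g]` the genotype frequency among
#'   adult males. `d = 0` (default) disables it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(K, n_generations, p0 = 0.5, initial_props = NULL,
                       sex_ratio = 0.5, n_replicates = 1L, seed = 1L,
                       freq_dep = 0) {
  if (!is.numeric(K) || length(K) != 1L || K <= 0 || K != round(K))
    stop("K must be a positive integer")
  if (!is.numeric(n_generations) || n_generations < 1 ||
      n_generations != round(n_generations))
    stop("n_generations must be a positive integer")
  if (is.null(initial_props)) {
    if (!is.numeric(p0) || p0 < 0 || p0 > 1)
      stop("p0 must lie in [0, 1]")
    initial_props <- c(p0^2, 2 * p0 * (1 - p0), (1 - p0)^2)
  }
  initial_props <- named_geno(initial_props)
  if (any(initial_props < 0) || abs(sum(initial_props) - 1) > 1e-9)
    stop("initial genotype proportions must be non-negative and sum to 1")
  if (!is.numeric(sex_ratio) || sex_ratio <= 0 || sex_ratio >= 1)
    stop("sex_ratio must lie strictly between 0 and 1")
  if (!is.numeric(freq_dep) || freq_dep < 0)
    stop("freq_dep must be non-negative")
  structure(list(K = as.integer(K),
                 n_generations = as.integer(n_generations),
                 initial_props = initial_props,
                 sex_ratio = sex_ratio,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed),
                 freq_dep = freq_dep),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "Simulation config: K = %d eggs, %d generations, %d replicate(s), seed %d\n",
    x$K, x$n_generations, x$n_replicates, x$seed))
  cat(sprintf("  initial genotype proportions: AA %.4f, AB %.4f, BB %.4f\n",
              x$initial_props[1], x$initial_props[2], x$initial_props[3]))
  cat(sprintf("  sex ratio %.2f, frequency-dependence d = %g\n",
              x$sex_ratio, x$freq_dep))
  invisible(x)
}

#' Read and write parameter files
#'
#' Parameter files are YAML with up to four sections: `fitness`
#' (`S_f`, `S_m`, `T_f`, `T_m`, `V`, `E`), `development` (`mu_f`, `mu_m`,
#' `c`), `habitat` (`A_mean`, `A_var`) and `simulation` (fields of
#' [sim_config()]). The bundled file `lab_default.yaml`
#' (`system.file("extdata", "lab_default.yaml", package = "coelosim")`)
#' reproduces the laboratory-fitted set exactly.
#'
#' @param path Path to a YAML parameter file.
#' @return `read_params()` returns a list with any of the elements
#'   `fitness`, `development`, `habitat`, `simulation` present in the file,
#'   each converted to its parameter class.
#' @export
read_params <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- list()
  if (!is.null(raw$fitness)) {
    f <- raw$fitness
    out$fitness <- fitness_params(S_f = f$S_f, S_m = f$S_m,
                                  T_f = f$T_f, T_m = f$T_m,
                                  V = f$V %||% 0.3, E = f$E %||% 70)
  }
  if (!is.null(raw$development)) {
    d <- raw$development
    out$development <- development_params(mu_f = d$mu_f, mu_m = d$mu_m,
                                          c = d$c %||% 0.5)
  }
  if (!is.null(raw$habitat)) {
    h <- raw$habitat
    out$habitat <- habitat_params(A_mean = h$A_mean, A_var = h$A_var %||% 2)
  }
  if (!is.null(raw$simulation)) {
    s <- raw$simulation
    out$simulation <- sim_config(
      K = s$K, n_generations = s$n_generations,
      p0 = s$p0 %||% 0.5, initial_props = s$initial_props,
      sex_ratio = s$sex_ratio %||% 0.5,
      n_replicates = s$n_replicates %||% 1L,
      seed = s$seed %||% 1L, freq_dep = s$freq_dep %||% 0)
  }
  out
}

#' @rdname read_params
#' @param params A list as returned by [read_params()] (any subset of the
#'   four sections).
#' @export
write_params <- function(params, path) {
  raw <- list()
  if (!is.null(params$fitness)) {
    fp <- params$fitness
    raw$fitness <- list(S_f = unname(fp$S["f", ]), S_m = unname(fp$S["m", ]),
                        T_f = unname(fp$T["f", ]), T_m = unname(fp$T["m", ]),
                        V = fp$V, E = fp$E)
  }
  if (!is.null(params$development)) {
    dp <- params$development
    raw$development <- list(mu_f = unname(dp$mu["f", ]),
                            mu_m = unname(dp$mu["m", ]), c = dp$c)
  }
  if (!is.null(params$habitat)) {
    hp <- params$habitat
    raw$habitat <- list(A_mean = hp$A_mean, A_var = hp$A_var)
  }
  if (!is.null(params$simulation)) {
    s <- params$simulation
    raw$simulation <- list(K = s$K, n_generations = s$n_generations,
                           initial_props = unname(s$initial_props),
                           sex_ratio = s$sex_ratio,
                           n_replicates = s$n_replicates, seed = s$seed,
                           freq_dep = s$freq_dep)
  }
  yaml::write_yaml(raw, path)
  invisible(path)
}
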