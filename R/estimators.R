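#' Alpha allele frequency from genotype counts
#'
#' @param counts Genotype counts in order AA, AB, BB (names optional).
#' @return `p = (2 n_AA + n_AB) / (2 N)`.
#' @examples
#' allele_frequency(c(25, 50, 25))   # 0.5
#' @export
allele_frequency <- function(counts) {
  counts <- named_geno(counts)
  N <- sum(counts)
  if (N <= 0) stop("allele frequency undefined for a zero total count")
  unname((2 * counts["AA"] + counts["AB"]) / (2 * N))
}

#' Hardy-Weinberg genotype proportions
#'
#' @param p Alpha allele frequency in `[0, 1]`.
#' @return Named proportions `(p^2, 2 p (1 - p), (1 - p)^2)`.
#' @export
hw_expected <- function(p) {
  if (!is.numeric(p) || p < 0 || p > 1) stop("p must lie in [0, 1]")
  c(AA = p^2, AB = 2 * p * (1 - p), BB = (1 - p)^2)
}

#' Relative survival from egg and adult proportions
#'
#' The ratio of a genotype's proportion among adults to its proportion
#' among the eggs it emerged from; 1 for all genotypes means equal
#' survival. With `normalize = TRUE` ratios are rescaled so the best
#' genotype has value 1 (the per-sex convention of the fitted parameter
#' table).
#'
#' @param egg_props,adult_props Genotype proportions (AA, AB, BB).
#' @param normalize Rescale so the maximum ratio is 1.
#' @return A list of class `survival_estimate` with `raw` and `normalized`
#'   ratios; genotypes absent from both stages are `NA`.
#' @examples
#' relative_survival(c(0.25, 0.5, 0.25), c(0.20, 0.55, 0.25))
#' @export
relative_survival <- function(egg_props, adult_props, normalize = TRUE) {
  e <- named_geno(egg_props); a <- named_geno(adult_props)
  if (any(e == 0 & a > 0))
    stop("genotype absent in eggs but present in adults: ",
         paste(GENOTYPES[e == 0 & a > 0], collapse = ", "))
  raw <- ifelse(e == 0, NA_real_, a / e)
  norm <- raw
  if (normalize && any(!is.na(raw))) norm <- raw / max(raw, na.rm = TRUE)
  structure(list(raw = raw, normalized = norm), class = "survival_estimate")
}

#' @export
print.survival_estimate <- function(x, ...) {
  cat("Relative survival (adult/egg proportion ratio):\n")
  print(rbind(raw = round(x$raw, 4), normalized = round(x$normalized, 4)))
  invisible(x)
}

#' Deviation of egg proportions from random mating
#'
#' Compares egg genotype proportions to the Hardy-Weinberg expectation
#' computed from the parental adults' allele frequency; the fractional
#' deviation `egg_prop / expected - 1` is 0 under random mating and equal
#' reproduction, positive for an excess, negative for a deficit.
#'
#' @param parent_adult_counts Genotype counts among the parental adults.
#' @param egg_counts Genotype counts (or proportions) among their eggs.
#' @return A list of class `mating_deviation` with `p_parents`, `expected`
#'   proportions and `deviation` per genotype (`NA` where the expectation
#'   is 0, i.e. when `p_parents` is 0 or 1).
#' @export
mating_deviation <- function(parent_adult_counts, egg_counts) {
  p <- allele_frequency(parent_adult_counts)
  exp_props <- hw_expected(p)
  eggs <- named_geno(egg_counts)
  tot <- sum(eggs)
  if (tot <= 0) stop("egg counts must have a positive total")
  obs <- eggs / tot
  dev <- ifelse(exp_props > 0, obs / exp_props - 1, NA_real_)
  structure(list(p_parents = p, expected = exp_props, observed = obs,
                 deviation = dev),
            class = "mating_deviation")
}

#' @export
print.mating_deviation <- function(x, ...) {
  cat(sprintf("Parental alpha frequency: %.4f\n", x$p_parents))
  print(rbind(expected = round(x$expected, 4),
              observed = round(x$observed, 4),
              deviation = round(x$deviation, 4)))
  invisible(x)
}

#' Chi-squared test of random mating and Fisher combination
#'
#' `random_mating_test()` is a Pearson goodness-of-fit test of observed
#' egg genotype counts against expected proportions (typically the
#' Hardy-Weinberg proportions of the parental generation); categories
#' with zero expectation are dropped and the degrees of freedom reduced
#' accordingly. `combine_pvalues()` pools per-replicate p-values, by
#' default with Fisher's method (`-2 * sum(log p)` against a chi-squared
#' distribution with `2k` degrees of freedom); Stouffer's Z is available
#' as an alternative.
#'
#' @param observed Observed genotype counts.
#' @param expected_props Expected genotype proportions.
#' @return A list with `statistic`, `df` and `p_value`.
#' @export
random_mating_test <- function(observed, expected_props) {
  obs <- named_geno(observed)
  ep <- named_geno(expected_props)
  if (sum(obs) <= 0) stop("all-zero observed counts")
  if (any(ep < 0)) stop("expected proportions must be non-negative")
  keep <- ep > 0
  if (any(obs[!keep] > 0))
    stop("observed counts in categories with zero expectation")
  obs <- obs[keep]
  ep <- ep[keep] / sum(ep[keep])
  exp_counts <- ep * sum(obs)
  stat <- sum((obs - exp_counts)^2 / exp_counts)
  df <- sum(keep) - 1L
  list(statistic = unname(stat), df = df,
       p_value = unname(stats::pchisq(stat, df, lower.tail = FALSE)))
}

#' @rdname random_mating_test
#' @param p Vector of p-values in `(0, 1]`.
#' @param method `"fisher"` (default) or `"stouffer"`.
#' @export
combine_pvalues <- function(p, method = c("fisher", "stouffer")) {
  method <- match.arg(method)
  p <- p[!is.na(p)]
  if (length(p) == 0) stop("no p-values to combine")
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  if (method == "fisher") {
    stat <- -2 * sum(log(p))
    stats::pchisq(stat, df = 2 * length(p), lower.tail = FALSE)
  } else {
    z <- sum(stats::qnorm(p, lower.tail = FALSE)) / sqrt(length(p))
    stats::pnorm(z, lower.tail = FALSE)
  }
}

## Pull a named count vector (AA, AB, BB) out of a count table slice.
counts_from_table <- function(tab) {
  out <- stats::setNames(numeric(3), GENOTYPES)
  if (nrow(tab) == 0) return(out)
  agg <- stats::aggregate(count ~ genotype, data = tab, FUN = sum)
  out[agg$genotype] <- agg$count
  out
}

#' Per-replicate fitness estimators over a genotype count table
#'
#' Applies the survival and mating-deviation estimators to every
#' (replicate, generation) cell of a genotype count table (see
#' [read_count_table()] for the format). Survival compares adult to egg
#' proportions within a generation (sex-pooled, or per sex where sexed
#' adult counts exist); mating deviation compares egg proportions at
#' generation g to the Hardy-Weinberg expectation from the adults of
#' generation g - 1.
#'
#' @param tab A genotype count table (data frame with columns `replicate`,
#'   `generation`, `stage`, `sex`, `genotype`, `count`).
#' @return A list of two data frames: `survival` (replicate, generation,
#'   sex, genotype, raw and normalized ratios) and `mating` (replicate,
#'   generation, genotype, deviation).
#' @export
estimate_fitness_components <- function(tab) {
  validate_count_table(tab)
  surv <- list(); mat <- list()
  for (rep_id in unique(tab$replicate)) {
    rt <- tab[tab$replicate == rep_id, ]
    gens <- sort(unique(rt$generation))
    for (g in gens) {
      gt <- rt[rt$generation == g, ]
      eggs <- counts_from_table(gt[gt$stage == "egg", ])
      for (sx in c("all", "f", "m")) {
        ad <- gt[gt$stage == "adult", ]
        if (sx != "all") ad <- ad[ad$sex == sx, ]
        adults <- counts_from_table(ad)
        if (sum(eggs) > 0 && sum(adults) > 0 &&
            !any(eggs == 0 & adults > 0)) {
          est <- relative_survival(eggs / sum(eggs), adults / sum(adults))
          surv[[length(surv) + 1L]] <- data.frame(
            replicate = rep_id, generation = g, sex = sx,
            genotype = GENOTYPES, raw = unname(est$raw),
            normalized = unname(est$normalized), stringsAsFactors = FALSE)
        }
      }
      ## mating deviation: eggs at g vs adults at g - 1
      prev <- rt[rt$generation == g - 1 & rt$stage == "adult", ]
      parents <- counts_from_table(prev)
      if (sum(eggs) > 0 && sum(parents) > 0) {
        p <- allele_frequency(parents)
        if (p > 0 && p < 1) {
          md <- mating_deviation(parents, eggs)
          mat[[length(mat) + 1L]] <- data.frame(
            replicate = rep_id, generation = g, genotype = GENOTYPES,
            deviation = unname(md$deviation), stringsAsFactors = FALSE)
        }
      }
    }
  }
  list(survival = do.call(rbind, surv) %||%
         data.frame(replicate = character(), generation = integer(),
                    sex = character(), genotype = character(),
                    raw = numeric(), normalized = numeric()),
       mating = do.call(rbind, mat) %||%
         data.frame(replicate = character(), generation = integer(),
                    genotype = character(), deviation = numeric()))
}

#' Replicate-level bootstrap of an estimator
#'
#' Resamples replicates with replacement and recomputes a statistic of
#' the estimator tables, giving a simple percentile interval.
#'
#' @param tab A genotype count table.
#' @param statistic Function mapping the result of
#'   [estimate_fitness_components()] to a numeric vector.
#' @param n_boot Number of bootstrap resamples.
#' @return Matrix with rows `lower`, `upper` (2.5/97.5 percentiles).
#' @export
bootstrap_estimates <- function(tab, statistic, n_boot = 200) {
  reps <- unique(tab$replicate)
  draws <- replicate(n_boot, {
    pick <- sample(reps, length(reps), replace = TRUE)
    boot <- do.call(rbind, lapply(seq_along(pick), function(i) {
      b <- tab[tab$replicate == pick[i], ]
      b$replicate <- paste0("b", i)
      b
    }))
    statistic(estimate_fitness_components(boot))
  })
  if (is.null(dim(draws))) draws <- matrix(draws, nrow = 1)
  apply(draws, 1, stats::quantile, probs = c(0.025, 0.975), na.rm = TRUE)
}
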