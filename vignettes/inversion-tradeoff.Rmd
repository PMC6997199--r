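---
title: "Modelling an inversion polymorphism under a survival-reproduction trade-off"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling an inversion polymorphism under a survival-reproduction trade-off}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coelosim)
```

## The biological problem

Natural populations of the seaweed fly *Coelopa frigida* are polymorphic for
a large chromosomal inversion. Recombination between the two arrangements,
called α and β, is suppressed, so the inversion is inherited like a single
Mendelian locus with three genotypes (αα, αβ, ββ; encoded `AA`, `AB`, `BB`
throughout this package, with α the reference allele whose frequency `p` is
reported). The arrangements pull fitness in opposite directions:

* **β aids larval survival.** ββ and αβ larvae survive the egg-to-adult
  stage better than αα, and ββ males develop much faster (8.8 days against
  12.8 for αα males at 25°C and low density). In the wild the larval
  habitat — the wrackbed, a deposit of decomposing seaweed — is routinely
  destroyed by tides and storms, so slow developers risk never reaching
  adulthood.
* **α aids reproduction.** Females carrying α lay more eggs, and large αα
  males strongly out-compete small ββ males for matings.

This antagonistic pleiotropy between fitness components is a candidate
mechanism of balancing selection. The package implements an
individual-based model of the life cycle to ask when the trade-off
maintains the polymorphism, and what it looks like at the level of total
fitness (overdominance, sexual antagonism).

## The generation cycle

Generations are non-overlapping, each with a growth and a reproduction
phase.

**Growth.** Every egg has a genotype and a sex. It survives to the larval
stage with probability `V * S[sex, genotype]`, the product of a global
egg-to-adult viability (`V = 0.3`) and a relative, sex-by-genotype survival
weight scaled so the best genotype in each sex has weight 1. A surviving
larva draws an individual development time `D_i` — the cube root of the
product of three independent uniforms on `[mu(1-c), mu(1+c)]`, with `mu`
the sex-by-genotype mean and `c = 0.5` — and an individual habitat
availability `A_i ~ U[A_mean - A_var, A_mean + A_var]`. It matures into an
adult only if `D_i < A_i`.

**Reproduction.** Every adult female mates and lays `round(E *
T_f[genotype])` eggs (`E = 70`). For each female one father is drawn with
probability proportional to `N_m[g] * T_m[g]` — male genotype counts
weighted by relative mating success — independently across females, so
males can sire multiple broods. Each egg takes one uniformly chosen allele
from each parent; its sex is female with probability 0.5. A uniform subset
of `K` eggs (the census) initiates the next generation, mirroring either
the experimental protocol or a carrying capacity.

Generation 0 is the founding egg cohort together with the adults emerging
from it; each reproduction step increments the generation counter, and egg
counts are recorded before the census so the laid pool is observable.

## Parameters

The laboratory-fitted default set (`lab_params()`, also bundled as
`inst/extdata/lab_default.yaml`) is:

| quantity | αα | αβ | ββ |
|---|---|---|---|
| `S` males | 0.81 | 1.00 | 0.88 |
| `S` females | 0.71 | 0.90 | 1.00 |
| `T` males | 1.00 | 0.55 | 0.10 |
| `T` females | 1.00 | 0.97 | 0.87 |
| `mu` males (days) | 12.8 | 10.3 | 8.8 |
| `mu` females (days) | 9.0 | 8.7 | 9.0 |

with `V = 0.3`, `E = 70`, `c = 0.5` and a laboratory habitat of
`A_mean = 30`, `A_var = 2` days — effectively unlimited, since the slowest
possible development time is `1.5 * 12.8 = 19.2` days. The male mating
weights (1, 0.55, 0.1) are the fitted 10-fold αα advantage with a
co-dominant heterozygote; the female weights come directly from fecundity
counts (70, 68, 61 eggs, rescaled).

The same table can be generated from the theoretical parameterization
(`theoretical_params()` / `from_theoretical()`): selection coefficients
`s_m, s_f` on survival (acting against α) and `t_m, t_f` on reproduction
(acting against β), with dominance coefficients `H_s`, `H_t`. For example
`t_m = 0.9, H_t = 0.5` reproduces the male weights above. This six-axis
space is what the theoretical sweeps explore.

## Design choices in ambiguous corners

Several model details admit more than one reading; the package fixes them
as follows and exposes the choice where reasonable.

* **Development-time distribution.** "Cube root of three uniform draws" is
  implemented as the cube root of the *product* (the geometric mean
  construction). Its mean is `mu * (0.75 * ((1+c)^{4/3} - (1-c)^{4/3}) /
  (2c))^3 ≈ 0.971 mu` at `c = 0.5`, and its support `[mu(1-c), mu(1+c)]`,
  so the genotype ordering that drives every result is preserved under any
  of the alternative readings.
* **`A_var` is a half-width**, giving support `A_mean ± A_var`; the
  symmetric reading of "mean and variability". Each larva draws its own
  `A_i`: the shared mean encodes the wrackbed being washed away for
  everyone at once, while the individual spread encodes laying-date and
  patch heterogeneity.
* **Egg numbers are deterministic** (`round(E * T_f)`): the stated product
  is not a sampling law, and keeping it deterministic attributes all
  variance to the explicitly stochastic steps.
* **Negative frequency dependence on male success** is a pluggable hook,
  `T_m[g] * (1 - d * f_m[g])` with `d >= 0` and `f_m` the male genotype
  frequency (`d = 0` by default). Only the qualitative behaviour —
  penalising common male genotypes — is specified by the biology; the
  exact functional form used in the original analyses is not published in
  the main text, so this stand-in is deliberately simple.
* **Extinction** (a generation with no adults of one sex, or no eggs) ends
  a replicate with a flagged, truncated trajectory rather than an error;
  sweeps tally these, mirroring the population crashes seen in real
  replicates.
* **Medium/high-density survival presets are config-supplied**
  (`density_preset()`): their numeric values come from supplementary
  material we do not reproduce, so hard-coding them would invent data. The
  low-density preset is the laboratory table itself.

## The deterministic oracle

`deterministic_recursion()` iterates the expected-value dynamics of an
infinite population: effective survival `V * S * P(D < A)` per sex and
genotype (with `P(D < A)` computed by numerical integration — composite
Simpson on a fixed fine grid, which is robust to the kinks the clamped
uniform cdf introduces), then maternal and paternal α-gamete frequencies
weighted by `T_f` and `T_m`, whose product gives the next egg genotype
proportions. It is used three ways: as an independent test oracle
(stochastic mean trajectories at large `K` must agree with it), to predict
qualitative signs (e.g. the egg-stage excess of αα), and as a cheap
self-fit reference for the nRMSE machinery.

```{r recursion}
p <- lab_params()
rec <- deterministic_recursion(p$fitness, p$development, p$habitat,
                               initial_props = hw_expected(0.32),
                               n_generations = 5)
subset(rec, stage == "adult" & genotype == "AA",
       c(generation, proportion, p_alpha))
```

## Estimators

From egg/adult genotype count tables (the observable output of a
genotyping experiment) the package computes: allele frequencies;
relative survival, the ratio of adult to egg genotype proportions
(optionally normalized so the best genotype is 1, the convention of the
fitted table); the deviation from random mating, the ratio of egg
proportions to Hardy-Weinberg expectations from the parental adults,
minus 1; and Pearson χ² tests of those expectations with Fisher (or
Stouffer) combination across replicates. Proportions are always computed
within a (replicate, generation, stage, sex) cell; sex-pooled estimates
sum counts first. Replicate-level ratios are pooled by unweighted
averaging.

## Model fitting

The fit of a scenario to observed trajectories is the normalized RMSE
(`nrmse()`), computed per variable over generations 1-5 for the six
genotype-proportion series (AA/AB/BB in eggs and adults), averaged over
variables and over simulation replicates (30 by default). Normalization
divides the RMSE by the mean of the observed series; mean-normalization is
the stable choice for short proportion series whose range can be close to
zero, and range-normalization is available via `norm = "range"`. Observed
experimental replicates are averaged per generation before comparison
(`pool = FALSE` scores each separately). `grid_search_male_success()`
scans `T_bb_m` with the heterozygote at the co-dominant midpoint
`(1 + T_bb_m)/2` (a dominance variant can be injected), and
`compare_scenarios()` applies Welch t-tests on per-replicate mean nRMSE
with Benjamini-Hochberg correction.

## Outcomes and mechanism classification

Total fitness is the product `W = S * T` per sex and genotype, with allele
fitnesses `w_alpha = W_AA + W_AB/2` and `w_beta = W_BB + W_AB/2` (their
sum equals the sum of the three `W` exactly, a convenient invariant).
Overdominance holds in a sex when `W_AB` strictly exceeds both
homozygotes; sexual antagonism when the sexes strictly favour different
alleles. Ties count as absent — under continuous parameters they are
measure-zero, and the strict reading keeps the flags conservative. On the
fitted laboratory values this yields female overdominance (0.873 against
0.71 and 0.87), no male overdominance (0.81, 0.55, 0.088 is monotone) and
sexual antagonism (males favour α, females β).

A trajectory's fate (`classify_polymorphism()`) is read from the final
generation: fixed if `p` is exactly 0 or 1, extinct if flagged, otherwise
maintained; "equilibrium" proportions are the mean over the final 20
generations (a pragmatic window — the original analyses report equilibria
without defining one; the window is a parameter). In realistic sweeps the
mechanism flags are computed from the configured `S * T` and, optionally,
from the realized survival extracted from the trajectories, because
habitat censoring changes realized survival away from its configured
value; `realized_relative_survival()` therefore averages per-generation
adult/egg proportion ratios (the census between the laid pool and the
next cohort is unbiased in composition, which makes proportion ratios the
correct comparison) normalized to ββ.

## Synthetic experiments

`make_experiment_dataset()` emulates the genotyping experiment: it runs
the simulator per replicate and genotypes a multinomial subsample at every
generation — 28-51 eggs (sex-pooled, as eggs cannot be sexed) and 40-95
adults (sexed) per replicate by default, the depths of the real
experiment, drawn uniformly from those ranges. This gives estimator and
fitting code observable data with known ground truth. The generator
reproduces finite genotyping depth and demographic stochasticity; it does
not model genotyping error, missing data, substrate or temperature
effects, so tests passing on synthetic data say nothing about those
failure modes in real data.

## Problem sizes used in the checks

The packaged tests and the acceptance script run at the scale of the
original laboratory design where that is cheap — 30 replicates, `K =
1000`, five generations, initial α frequency 0.32 in Hardy-Weinberg
proportions — and at reduced scale for long-horizon questions: oracle
agreement uses `K = 1e5` over a few generations; the habitat-variability
sweep uses a 3 × 5 grid of male success and habitat duration with 10
replicates per point, `K = 1000` and 100 generations; the β-fixation
scenario uses 15 replicates of 100 generations. These sizes were chosen to
make the qualitative claims they check statistically unambiguous while
keeping a full run of the suite in minutes; the trends involved (fixation
under selection against α males, the widening of the polymorphism region
with `A_var`) are already stable at these scales.

## Known limitations

* Generations are strictly non-overlapping and there is no explicit space,
  migration, mutation, or within-inversion recombination.
* Density affects survival only through preset parameter blocks, not as a
  dynamic feedback within a run.
* The frequency-dependence hook is a stand-in with a simple linear form.
* The mixed-model significance machinery used on real experimental data is
  out of scope; the package emits tidy tables for external statistics and
  retains only the scenario-comparison t-test on simulated nRMSE
  replicates.
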