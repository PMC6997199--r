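# coelosim

Individual-based simulation of a chromosomal inversion polymorphism under
an antagonistic survival–reproduction trade-off, modelled on the seaweed
fly *Coelopa frigida*.

## The problem

*C. frigida* populations are polymorphic for a large inversion that
behaves as a single Mendelian locus with two alleles, α and β. The alleles
trade off across fitness components: β improves larval survival and
shortens development (critical when the larval habitat — the wrackbed —
can be washed away by tides and storms before slow larvae mature), while α
improves reproduction (higher female fecundity, a large mating advantage
of big αα males). `coelosim` is for population geneticists who want to
simulate these dynamics, estimate fitness components from genotyping data,
fit scenarios to observed trajectories, and map where such antagonistic
pleiotropy maintains the polymorphism.

## The model

Non-overlapping generations with a growth and a reproduction phase:

* an egg of sex *s* and genotype *XX* survives with probability
  `V · S_XX-s` (global viability times relative survival);
* a larva matures only if its development time `D_i` (cube root of the
  product of three uniforms on `[μ(1−c), μ(1+c)]`, means μ per sex and
  genotype) is shorter than its habitat availability
  `A_i ~ U[A_mean − A_var, A_mean + A_var]`;
* every female lays `round(E · T_XX-f)` eggs; each brood's father is drawn
  with probability ∝ `N_m[XX] · T_XX-m` (males may mate repeatedly);
  inheritance is Mendelian; a census of `K` eggs starts the next
  generation.

Total fitness is `W_XX-s = S_XX-s · T_XX-s`, with allele fitnesses
`w_α-s = W_αα-s + ½ W_αβ-s` and `w_β-s = W_ββ-s + ½ W_αβ-s`. Balancing-
selection mechanisms are classified from these: overdominance when
`w_αβ-s` strictly exceeds both homozygotes, sexual antagonism when the
sexes strictly favour different alleles. A deterministic
infinite-population recursion of the same life cycle serves as a
verification oracle. Fit to observed genotype-proportion trajectories is
scored by normalized RMSE over six variables (αα/αβ/ββ in eggs and
adults, generations 1–5), averaged over 30 simulation replicates.

## Worked example

Simulate the five-generation laboratory scenario (fitted parameter table,
`K = 1000`, initial α frequency 0.32 in Hardy–Weinberg proportions):

```r
library(coelosim)
p <- lab_params()
cfg <- sim_config(K = 1000, n_generations = 5, p0 = 0.32, seed = 42,
                  n_replicates = 30)
trs <- run_replicates(cfg, p$fitness, p$development, p$habitat)
p5 <- sapply(trs, function(tr) {
  ap <- p_alpha_series(tr, "adult")
  ap$p_alpha[ap$generation == 5]
})
sprintf("mean adult alpha frequency at G5: %.1f%%", mean(100 * p5))
#> [1] "mean adult alpha frequency at G5: 67.6%"
print(trs[[1]])
#> Trajectory: 5 generations recorded (seed 42008045)
#> Adult alpha frequency by generation:
#>     0     1     2     3     4     5
#> 0.299 0.404 0.519 0.595 0.660 0.688
```

The α frequency climbs from ~30% to ~68% in five generations — the rise
observed in the real experiment (58–75% at generation 5) — even though αα
larvae survive *worst*: the reproductive advantage outweighs the survival
cost. The mechanism is visible in total fitness:

```r
total_fitness(p$fitness)
#> Total fitness W = S * T:
#>     AA    AB    BB
#> f 0.71 0.873 0.870
#> m 0.81 0.550 0.088
#> Allele fitness:
#>    alpha   beta
#> f 1.1465 1.3065
#> m 1.0850 0.3630
#> Overdominance: f = TRUE, m = FALSE; sexual antagonism = TRUE
```

Females are overdominant for total fitness and the sexes favour opposite
alleles — balancing selection emerging from the trade-off.

A command-line interface wraps the same functions
(`exec/coelosim simulate|sweep|fit|estimate|synth`; see `?cf_cli`), and
`vignettes/inversion-tradeoff.Rmd` documents the model, its assumptions
and design choices.

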