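# Shared fixtures: small parameter sets and a deterministic count table.

lab <- lab_params()

neutral_fitness <- function(V = 1, E = 10) {
  fitness_params(S_f = c(1, 1, 1), S_m = c(1, 1, 1),
                 T_f = c(1, 1, 1), T_m = c(1, 1, 1), V = V, E = E)
}

flat_development <- function(mu = 5, c = 0) {
  development_params(mu_f = rep(mu, 3), mu_m = rep(mu, 3), c = c)
}

wide_habitat <- function() habitat_params(A_mean = 30, A_var = 0)

tiny_count_table <- function() {
  expand_tab <- expand.grid(
    replicate = "R1", generation = 0:1, stage = c("egg", "adult"),
    sex = "unknown", genotype = c("AA", "AB", "BB"),
    stringsAsFactors = FALSE)
  expand_tab$sex[expand_tab$stage == "adult"] <- "f"
  expand_tab <- expand_tab[order(expand_tab$generation, expand_tab$stage), ]
  expand_tab$count <- c(25L, 50L, 25L,  20L, 55L, 25L,
                        30L, 50L, 20L,  28L, 52L, 20L)
  expand_tab
}
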