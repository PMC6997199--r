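# Laboratory-fitted default parameter set: sex- and genotype-specific
# relative survival (S) and reproductive success (T) in genotype order
# AA (alpha/alpha), AB, BB; global viability V; eggs per female E;
# development-time means (days) and variation coefficient; habitat
# duration (effectively unlimited in the laboratory).
fitness:
  S_f: [0.71, 0.90, 1.0]
  S_m: [0.81, 1.0, 0.88]
  T_f: [1.0, 0.97, 0.87]
  T_m: [1.0, 0.55, 0.1]
  V: 0.3
  E: 70
development:
  mu_f: [9.0, 8.7, 9.0]
  mu_m: [12.8, 10.3, 8.8]
  c: 0.5
habitat:
  A_mean: 30
  A_var: 2
simulation:
  K: 1000
  n_generations: 5
  p0: 0.32
  sex_ratio: 0.5
  n_replicates: 30
  seed: 1
  freq_dep: 0
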