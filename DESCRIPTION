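Package: coelosim
Title: Individual-Based Simulation of an Inversion Polymorphism Under a
    Survival-Reproduction Trade-Off
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Forward-time, individual-based simulation of a chromosomal
    inversion polymorphism in the seaweed fly Coelopa frigida, where the
    two arrangements trade larval survival against adult reproductive
    success. Provides the two-phase generation cycle (viability selection,
    development-time censoring by habitat availability, fecundity and
    weighted mate choice with Mendelian inheritance), a deterministic
    infinite-population recursion as a verification oracle, estimators of
    fitness components from egg/adult genotype count tables (relative
    survival, deviation from random mating, chi-squared tests with
    combined probabilities), trajectory fitting by normalized RMSE with a
    grid search over male mating success, total-fitness classification of
    emergent balancing-selection mechanisms (overdominance, sexual
    antagonism), parameter-space sweep drivers, and a synthetic-data
    generator emulating finite-depth genotyping experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
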