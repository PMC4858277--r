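Package: staghunt
Title: Embodied and Game-Theoretic Simulation of Stag Hunt Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the evolutionary emergence of cooperative hunting in
    the stag hunt coordination game under two genotype-phenotype mappings: an
    embodied model in which two wheeled hunters controlled by evolved neural
    networks forage for hares and stags in a walled arena, and the classical
    single-binary-locus game-theoretic model. Both models share a
    Wright-Fisher (fitness-proportionate) evolutionary regime with Gaussian
    or locus-flip mutation. Provides the arena physics and ray-cast sensor
    engine (in C++), named experimental conditions (pre-evolved hare hunters,
    random initialisation, solitary stag rewards, clonal pairing, prey
    density variants), replicator-dynamics analytics, per-generation run
    records as tibbles with broom-style tidiers and ggplot2 autoplot methods,
    and Mann-Whitney comparisons between conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    tidyr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    rlang,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
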