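Package: heterogame
Title: Game-Theoretic Models of Phenotypic Heterogeneity in Microbial
    Competition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a non-cooperative competition game between
    asexually reproducing microbe species. Species play mixed strategies:
    probability distributions of a scalar competitive ability on [0,1],
    scaled by population abundance and constrained to a mean competitive
    ability of at most one half. The package evaluates the multi-species
    zero-sum payoff functionals for finite-support and continuous
    strategies, classifies equilibrium strategies in closed form and
    verifies them against a best-response vertex-enumeration oracle,
    constructs counter-strategies that defeat any non-equilibrium
    strategy, and runs an individual-based stochastic tournament
    simulator with per-round trait reassignment to study coexistence,
    competitive exclusion and invasion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
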