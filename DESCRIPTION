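Package: toxwar
Title: Eco-Evolutionary Dynamics of Regulated Toxin Warfare in Bacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models pairwise competition between toxin-producing bacterial
    strains with an implicit-Euler solver for a Monod-limited resource
    competition ODE system, and embeds local competitions in
    metapopulation-level game theory: pairwise invasion analysis and
    evolutionarily stable strategy (ESS) search for constitutive toxin
    investment, grid tournaments that test whether sensing-regulated
    strategies (nutrient stress, quorum sensing, toxin sensing) stably
    invade constitutive producers or dominate a standing diversity of
    opponents, and a genetic algorithm for coevolving regulation
    strategies.  Results are returned as tibbles with broom-style tidiers
    and ggplot2 autoplot methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
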