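Package: waningvax
Title: Epidemic Dynamics with Waning Immunity and Recurrent Vaccination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying endemicity of an imperfectly immunizing
    pathogen under recurrent (booster) vaccination and waning immunity.
    Provides an exact event-driven individual-based simulator in which each
    infection carries a random infectiousness curve and each recovery or
    vaccination resets a random, non-decreasing susceptibility curve; a
    deterministic large-population limit solved as a system of Volterra
    integral equations with reconstruction of the age-structured densities;
    closed-form equilibrium analysis (disease-free and endemic equilibria,
    the endemic function and the endemic threshold); and a multigroup
    extension with next-generation matrices, critical vaccination fractions
    and fair-allocation analysis of a fixed dose budget between groups.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite
Config/testthat/edition: 3
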