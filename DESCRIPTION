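Package: eventpgf
Title: Event-Space Generating Functions for Linear Stochastic Population
    Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact and approximate solutions for Markov jump processes with
    linear (first-order) transition rates, formulated on the lattice of event
    counts rather than population numbers.  Provides the probability
    generating function of the event-count distribution via the method of
    characteristics (a small system of complex ODEs per transform point),
    closed forms for classic processes (pure death, linear birth-death) and
    for stage-structured developmental cascades with and without per-stage
    mortality (Erlang and hypoexponential stage durations), systematic
    short-time Poisson and multinomial (truncated Picard) approximation
    schemes with their fixed-step simulation algorithm, and independent
    oracles (Gillespie-type exact simulation, truncated master-equation
    integration) for validation.  Results are returned as tibbles with
    ggplot2 autoplot methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    Matrix,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
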