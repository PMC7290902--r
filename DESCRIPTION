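Package: frustgame
Title: Spatial Game Model of Depression Prevalence from Payoff Frustration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based model of depression arising from payoff frustration in
    a competitive environment. Individuals on a toroidal square lattice play an
    investing-in-education game against the labour market and receive one of six
    payoffs; an individual transitions from healthy to depressed when the mean
    payoff of the eight Moore neighbours exceeds the personal payoff by more
    than a gender-specific threshold. The package provides the payoff game and
    its prisoner's-dilemma ordering checks, exact-count population assignment
    on the torus, the one-shot transition rule with prevalence statistics, an
    exact multinomial enumeration oracle for prevalence under the i.i.d.
    approximation, an iterative threshold-calibration algorithm targeting an
    observed prevalence and a female/male prevalence-ratio band, post-calibration
    ensembles, and parameter sweeps over the payoff-category fractions. All
    results are tibbles; fitted objects have tidy(), glance() and autoplot()
    methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    optparse,
    readr,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
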