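Package: patrans
Title: Polyampholyte Translocation Through an Asymmetric Nanopore
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Metropolis Monte Carlo simulation and exact first-passage analysis
    of polyampholyte (and intrinsically disordered protein) translocation
    through the asymmetric alpha-hemolysin pore under an applied potential.
    Charge sequences of +/-1 monomers are mapped onto a one-dimensional free
    energy landscape built from a tabulated per-species pore profile; whole
    chain hopping dynamics yield translocation, rejection and trapping
    statistics, which are cross-checked against exact splitting probabilities
    and absorption-time distributions of the equivalent absorbing birth-death
    Markov chain. Ensemble tools compute translocation-time distributions,
    power-law tail exponents, trapped-population decay and outcome rates
    resolved by net charge and charge-window descriptors, alongside the
    closed-form disorder theory (disorder parameter mu, crossover lengths,
    barrier scales and net-charge criteria).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    seqinr,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
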