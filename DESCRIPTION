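Package: excitonet
Title: Kinetic Transition Network Analysis of Excitation Energy Transfer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing excitation energy transfer on kinetic
    transition networks such as the photosystem II supercomplex antenna
    system. Provides a labelled continuous-time Markov rate-matrix
    container with validation and equilibrium analysis, analytic
    first-passage-time distributions and moments via eigendecomposition
    of the substochastic transient generator, rejection-free kinetic
    Monte Carlo trajectory sampling, dwell-time profiles over protein
    subunits, in-silico subunit knockouts and non-photochemical-quenching
    sinks with committor (first-hit) probabilities, and translation of
    rate matrices into free-energy disconnectivity trees. Includes a
    generator for synthetic dimeric antenna networks with a flat,
    trap-terminated energy landscape and exact detailed balance.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    graphics,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
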