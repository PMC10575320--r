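Package: helixmc
Title: Replica-Exchange Monte Carlo and Microcanonical Analysis of Helical Homopolymers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Coarse-grained simulation and microcanonical analysis of helical
    homopolymers. Implements a bead-spring chain with FENE bonds, truncated and
    shifted Lennard-Jones interactions, and stiff bending and torsion potentials
    that stabilise helical secondary structure; a two-dimensional
    (temperature by torsion-strength) replica-exchange Metropolis sampler with
    local and global chain updates; multiple-histogram reweighting (WHAM) to the
    one- and two-dimensional density of states in log space; Savitzky-Golay
    smoothed microcanonical entropy derivatives with inflection-point detection
    and classification of phase transitions up to fourth order; and structural
    prevalence analysis over energy and a helix-bundling order parameter.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
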