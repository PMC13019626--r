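Package: erfr
Title: Fragment-Based Conformational Ensembles of Disordered Peptides
    with NMR Reweighting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds broad conformational ensembles of intrinsically
    disordered peptides by recombining short overlapping fragment
    conformers (fragment libraries are clustered by affinity propagation,
    joined by rigid-body superposition on the shared overlap residue,
    and filtered by a log-normal energy cutoff), then reweights the
    resulting sparse ensemble against NMR observables (3J(HN-HA)
    couplings back-calculated with the Karplus equation, ingested
    chemical-shift predictions) under a theta-regularised
    restraint/maximum-entropy objective. Ships a synthetic coil-library
    generator so the whole protocol runs without molecular dynamics
    input, plus diagnostics: Kish effective sample size, ensemble
    preservation, and weighted radius-of-gyration densities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    igraph,
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
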