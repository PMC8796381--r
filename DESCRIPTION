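Package: fluxscreen
Title: Constraint-Based Metabolic Modeling with Parallel Variant Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Data structures and analyses for constraint-based reconstruction
    and analysis (COBRA) of genome-scale metabolic models. Reads and writes
    models in the COBRA JSON dialect and reads SBML Level 3 'fbc' documents;
    assembles stoichiometric matrices; parses and evaluates boolean
    gene-protein-reaction rules; and solves the steady-state linear programs
    behind flux balance analysis, flux variability analysis, single- and
    pair-gene deletion screens and production envelopes with a built-in
    bounded-variable simplex solver. A composable screening framework applies
    grids of serializable model variants (knockouts, bound changes, objective
    changes) to a base model, runs any registered analysis on every variant in
    parallel, and collects the outputs into a dense multi-dimensional result
    array. Utilities join several member models into a multi-organism
    community model sharing an environment compartment, and deterministic
    generators produce synthetic models with known analytic optima for
    testing and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Matrix,
    methods,
    parallel,
    Rcpp,
    stats,
    tools,
    utils,
    xml2
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
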