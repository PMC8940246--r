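Package: gutbrainflux
Title: Coupled Constraint-Based and Whole-Body Pharmacokinetic Modeling of
    Gut-Derived Oxidative Toxins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds gut microbiome community metabolic models (bacterial
    members plus a host enterocyte joined through a shared lumen compartment),
    solves flux balance and flux variability analysis problems with a built-in
    bounded-variable simplex solver, computes multi-objective Pareto-optimal
    growth states by linear and weighted binary search, and couples the
    constraint-based organ models (gut community, brain) to a six-tissue
    permeability-limited whole-body pharmacokinetic transport model through a
    discretized exchange of reactive-oxygen-species fluxes and concentrations.
    Includes FVA-based model comparison statistics (mean shift, range change,
    pathway scores), secretion-product ranking, deterministic toy fixture
    generators, SBML import/export, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    methods,
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    deSolve,
    xml2,
    jsonlite,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    withr,
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
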