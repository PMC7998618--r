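Package: boolmod
Title: Probabilistic Boolean Network Models of Gene Co-Expression Module
    Drug Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds probabilistic Boolean network models of drug response
    from steady-state expression data and heterogeneous interaction
    resources, and predicts node interventions (knockout or constitutive
    activation) that up- or down-regulate gene co-expression modules.
    Provides network assembly from interaction tables with alias
    resolution, reference-based edge scoring and in-degree-adaptive
    pruning; BooleaBayes-style probabilistic rule inference with
    regulator-significance pruning and a sloppy-logic protein-activation
    solver for post-translational regulation; pseudo-attractor
    identification via the deterministic approximation of the inferred
    system; influence-index scoring of candidate interventions; and
    asynchronous random-walk simulations with Mann-Whitney/BH
    classification of intervention effects. A synthetic-data module
    generates ground-truth networks, condition-structured expression and
    noisy multi-resource interaction tables so the whole pipeline can be
    exercised offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
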