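Package: sbmlattice
Title: Critical Lattice Models, Ancestral Relations and Super-Brownian Limit
    Predictions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Event-driven simulators for critical interacting particle systems
    on the integer lattice (voter model, contact process, oriented
    percolation, critical branching random walk) equipped with their ancestral
    relation: the partial order tracing every occupied space-time point back
    to the single ancestor at the origin.  Provides the observables of the
    super-Brownian-motion scaling theory (survival probability, range and
    one-arm exit probability, Hausdorff metric on compact sets, modulus of
    continuity of ancestral paths, spatial moments) together with the
    closed-form and numerical limit predictions on the super-Brownian side:
    the canonical-measure survival law, the Yaglom exponential law, Laplace
    functionals of integrated mass, the blow-up solution of the semilinear
    problem that sets the one-arm constant, and random-walk escape
    probabilities.  Designed for desk-scale empirical probes of the limit
    theorems: every estimator is seeded, censoring-aware and reports
    Monte-Carlo standard errors.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
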