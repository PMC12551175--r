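Package: hilama
Title: High-Dimensional Mediation Analysis with Latent Confounding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates and tests exposure-mediator-outcome paths when both
    the exposures and the mediators are high-dimensional and unmeasured
    confounders may act densely on the observed variables. Latent
    confounding is removed by spectral decorrelation (trimming the top
    singular directions of the design), per-coefficient inference uses a
    decorrelated debiased-lasso estimator with nodewise projection
    directions, and indirect-effect paths are selected by MinScreen
    top-K screening, joint-significance (maxP) p-values and a
    Benjamini-Hochberg data-driven threshold with false discovery rate
    control. Includes a synthetic-data generator with factor-model
    confounding and ground-truth bookkeeping, plus a simulation and
    evaluation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    glmnet,
    parallel,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
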