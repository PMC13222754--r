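Package: panelnet
Title: Cross-Sectional and Temporal Network Models for Parenting and
    Child Irritability Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for network analyses of three-wave questionnaire panels
    on parenting behaviors, parenting stress and child irritability.
    Scores item-level responses into composites with model-based
    reliability (McDonald's omega, Spearman-Brown), estimates regularized
    partial-correlation networks (EBIC-selected graphical lasso) per group
    and wave, fits pooled-lag panel graphical vector autoregression models
    with stepwise pruning, SEM fit indices and case-bootstrap edge
    stability, and compares edge weights between groups and timepoints by
    permutation tests. Includes a synthetic three-group panel generator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
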