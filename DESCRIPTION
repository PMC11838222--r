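Package: pathwaycnn
Title: Pathway-Based Multi-Omics Image Classification with an Explainable
    Convolutional Network and Survival Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates multiple omics layers (for example copy number,
    expression and methylation) into per-sample "pathway-PC images" via
    class-specific, per-pathway principal component analysis; classifies
    long-term versus non-long-term cancer survivors with a compact
    convolutional neural network implemented in base R; explains predictions
    with a from-scratch gradient-based Shapley-value attributor rolled up to
    pathway and omics level; and extracts significant genes from significant
    pathways with Cox proportional hazards Wald tests.  A synthetic
    multi-omics generator with planted discriminative pathways and known
    log-hazard coefficients makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    Rcpp,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    survival,
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
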