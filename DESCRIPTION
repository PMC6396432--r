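Package: mdmrnet
Title: Connectome-Wide Association Analysis of Structural Brain Networks
    with Multivariate Distance Matrix Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Per-region multivariate distance matrix regression (MDMR) on
    white-matter structural connectivity matrices, with covariate-adjusted
    permutation inference (Freedman-Lane scheme), false discovery rate
    control across regions, randomization-based (delta) post-hoc
    attribution of multivariate associations to individual connections,
    nodal-strength group comparisons, and PLS-DA classification
    contrasting MDMR-selected key connections with the full connectome.
    Includes a synthetic connectome-cohort generator with planted,
    stage-progressive connectivity-pattern alterations so the whole
    pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    mixOmics
Suggests:
    testthat (>= 3.0.0),
    pROC,
    vegan,
    withr
Config/testthat/edition: 3
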