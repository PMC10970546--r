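Package: pairomics
Title: Paired Untargeted LC-MS Metabolomics Biomarker Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy workflow for biomarker discovery from paired untargeted
    LC-MS metabolomics feature tables: internal-standard normalization and
    QC-pool coefficient-of-variation filtering, paired volcano-plot feature
    selection, OPLS-DA modelling with cross-validated Q2, CV-ANOVA and
    permutation validation, VIP-based variable selection with jackknife
    confidence intervals, and adduct-arithmetic annotation of selected
    features against a compound library. Includes a synthetic-data generator
    that reproduces the statistical structure of a paired rodent serum
    metabolomics study design with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    mixOmics,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
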