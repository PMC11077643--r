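Package: gradientsig
Title: Ferroptosis-Versus-Apoptosis Gradient Gene Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives a ferroptosis-versus-apoptosis gradient gene signature
    from dose-gradient transcriptomic contrasts, optimizes compact biomarker
    panels by bootstrapped-aggregation ranking, classifies perturbation
    fold-change profiles by single-sample gene-set enrichment (ssGSEA) with
    k-nearest-neighbour and ROC-AUC evaluation, and stratifies patient
    cohorts by signature enrichment (k-means, Kaplan-Meier, log-rank, Cox
    proportional hazards). Ships a synthetic-data generator that plants
    known shared, ferroptosis-specific, apoptosis-specific and
    time-reversing gene modules so every stage can be validated against
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    limma,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
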