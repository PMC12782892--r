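Package: markergap
Title: Genomics-Assisted Prediction of Apple Fruit Storability from
    QTL-Based Markers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Marker-based genomics-assisted prediction (GAP) for apple
    fruit storability traits (flesh firmness and crispness at harvest and
    their retainabilities during cold storage). Estimates per-marker
    genotype effects and joint effects of interacting functional markers
    as deviations of genotype-class phenotype means from the training
    population grand mean, computes additive and non-additive
    genotype-predicted values, and evaluates prediction accuracy by
    seeded k-fold cross-validation (Pearson correlation between predicted
    and observed values). Includes retainability phenotyping from monthly
    storage series, genomic interval and genotype-frequency utilities,
    and a synthetic biparental/accession population generator with
    configurable additive, dominance and epistatic architectures for
    fully reproducible simulation studies.
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
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
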