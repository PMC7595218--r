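Package: pachycnv
Title: Deep-Phenotype Clustering and Pachychoroid Scoring of Choroidal
    Neovascularization
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Unsupervised stratification of unilateral choroidal
    neovascularization (CNV) from deep baseline phenotypes: feature
    standardization, principal component analysis, gap-statistic selection
    of the number of clusters, and k-means clustering separate a
    pachychoroid neovasculopathy (PNV-type) group from a conventional
    drusen-driven AMD-type group.  Includes the published 7-parameter CNV
    score (a logistic log-odds score on age, sex, choroidal vascular
    hyperpermeability, retinal thickness, subfoveal choroidal thickness of
    both eyes, and soft drusen), score-cutoff positive-predictive-value
    bins, last-observation-carried-forward imputation with adjusted linear
    regression of visual-acuity change on the score, and a synthetic
    two-latent-class cohort generator so the whole pipeline is testable
    without patient-level data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    Rcpp,
    jsonlite,
    rlang,
    readr,
    stats,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    cluster,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
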