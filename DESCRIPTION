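Package: afgrs
Title: Weighted Genetic Risk Score Analysis for Atrial Fibrillation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes a weighted allele-counting genetic risk score (GRS) for
    atrial fibrillation from a 12-SNP panel, with mean-dosage imputation of
    missing genotypes, quintile/tertile risk stratification, logistic-regression
    association analysis with clinical covariates, C-statistic comparison of
    nested risk models, per-SNP association scans, and a one-SNP-per-gene
    9-SNP score. Includes a synthetic cohort generator (Hardy-Weinberg
    genotypes with configurable linkage disequilibrium, clinical covariates,
    and logistic or quintile-gradient outcome models) and a Monte-Carlo power
    engine for quintile-gradient case-control designs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
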