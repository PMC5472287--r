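Package: psgrs
Title: Genetic Risk Scores for Psoriasis Case-Control Cohorts
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Construction and evaluation of weighted genetic risk scores
    (GRS) in case-control studies of psoriasis. Provides per-SNP allelic
    association testing with Woolf confidence intervals and
    Hardy-Weinberg equilibrium quality control, nested GRS panel
    construction weighted by in-sample log odds ratios, quartile
    dose-response analysis, ROC/AUC model comparison by DeLong's method,
    logistic-regression evaluation of variance explained and
    sub-phenotype associations, seeded internal validation, and power
    calculation for allelic tests. A synthetic cohort simulator
    generates genotype and phenotype data with a specified allele
    frequency and odds-ratio structure, including a linked SNP pair and
    missingness, so the whole pipeline can be exercised end to end
    without access to individual-level study data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
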