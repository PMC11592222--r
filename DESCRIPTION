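Package: melprs
Title: Polygenic Risk Score Analysis for Melanoma Case-Control Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes weighted-allele polygenic risk scores (PRS) from
    genotype VCFs and per-SNP effect-size tables, standardizes scores
    against a control series, and carries out the downstream case-control
    analyses used in melanoma risk studies: SNP panel quality control
    (strand-ambiguous SNP removal and pairwise-r2 LD pruning), decile risk
    stratification with crude and covariate-adjusted odds ratios from
    logistic regression, per-SD odds ratios for continuous scores, paired
    DeLong comparison of correlated ROC curves from nested models, and
    Kruskal-Wallis comparison of score distributions across phenotypic
    strata.  A seeded synthetic-cohort generator (Hardy-Weinberg genotypes,
    retrospective case-control sampling under a logistic disease model,
    score-linked phenotypes and multiple-primary-melanoma counts) allows
    the full pipeline to run and be tested without individual-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
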