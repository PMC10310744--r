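Package: coscreen
Title: Case-Only Screening for Gene-Gene Interactions in Multi-Center
    Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for genome-wide case-only (CO) screening of pairwise
    SNP genotype interactions on disease risk. Provides per-center
    case-only logistic regression with principal-component adjustment,
    stability-filtered random-effects (DerSimonian-Laird) meta-analysis
    with a two-stage screening protocol and Bonferroni thresholding,
    analytic and Monte-Carlo power calculations contrasting case-only
    with case-control interaction designs, haplotype-EM linkage
    disequilibrium audits (r-squared, D-prime) of the population
    independence assumption, supportive age-at-onset interaction and
    expression-direction statistics, and a synthetic multi-center
    cohort generator with Balding-Nichols population structure, a
    logistic disease model with a planted interaction, batch genotyping
    error, and imputation-style fractional dosages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse
Config/testthat/edition: 3
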