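Package: ipwgwas
Title: Participation-Bias Correction for Biobank Genetic Studies via
    Inverse-Probability Weighting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Constructs inverse-probability participation weights for a
    selected (non-representative) cohort by contrasting it with a
    representative reference sample, and propagates those weights through
    downstream statistical genetics: weighted least-squares genome-wide
    association scans with Huber-White (sandwich) variance, LD-score
    regression heritability and genetic correlation with block-jackknife
    difference tests, and inverse-variance-weighted Mendelian randomization
    with a selection correction. Ships a synthetic-cohort generator with
    known ground truth (genotypes in Hardy-Weinberg proportions with block
    LD, polygenic traits, a logistic participation mechanism over harmonized
    auxiliary variables) so the full workflow is testable without restricted
    individual-level biobank data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    glmnet,
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    sandwich
Config/testthat/edition: 3
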