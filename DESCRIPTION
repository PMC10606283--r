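Package: pleioscan
Title: Anchor-Centric Pleiotropy Scans, Signed Association Matrices and
    Cluster Analysis of Exome-Wide Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for pair-wise pleiotropy analysis centred on one anchor
    disease (Alzheimer's disease in the motivating application). Implements
    per-variant quality control (minor allele frequency, call rate and the
    Hardy-Weinberg exact test), univariate exome-wide association scans with
    additive coding and sex/age adjustment, Fisher's combined p-value test
    with tiered genome-wide/suggestive significance rules, construction of a
    signed p-value-category SNP-by-phenotype matrix, two-axis Ward
    hierarchical clustering with a correlation-distance validation pass, and
    classification of antagonistic genetic heterogeneity from effect-sign
    products and phenotype correlations. A seeded synthetic cohort generator
    with planted pleiotropic effects supports calibration and recovery
    testing of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    ape,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
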