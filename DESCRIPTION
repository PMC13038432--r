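Package: excluscope
Title: Mendelian Randomization Gene Prioritization and Spatial Immune-Exclusion Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage transcriptome-wide Mendelian randomization (TMR) candidate-gene
    prioritization with an SMR/HEIDI colocalization screen and risk-direction
    classification, together with spatial immune-exclusion statistics
    (k-nearest-neighbor neighborhood and nearest-neighbor distance statistics under
    coordinate-preserving permutation nulls) and the expression-stratification rules
    that link them (marker-positive cell classification, Wilcoxon marker screens,
    median dichotomization, immune-factor panels). Includes seeded synthetic-data
    generators emulating instrument sets, cis-locus summary statistics with LD,
    spatial spot lattices with planted patterns, sparse single-cell counts, and bulk
    cohorts, so the whole pipeline is testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
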