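Package: frailMR
Title: Two-Sample Mendelian Randomization of Serum Protein Status on the
    Deficit-Accumulation Frailty Index
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) of protein
    nutritional status (serum albumin, serum total protein) on the Rockwood
    deficit-accumulation frailty index. Reads and harmonizes GWAS summary
    statistics onto a common effect allele, implements five summary-data MR
    estimators (fixed-effect inverse-variance weighted, penalized-weight IVW,
    weighted median with parametric bootstrap, MR-Egger with pleiotropy
    intercept test, and MR-Lasso instrument selection with a heterogeneity
    stopping rule), instrument- and stratum-level Cochran's Q diagnostics,
    a frailty-index calculator with per-SNP genotype regressions, and a
    seeded synthetic two-sample cohort generator for validation of the whole
    pipeline. Ships the instrument set of the motivating analysis as a
    plain-text fixture together with a one-call reproduction report.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
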