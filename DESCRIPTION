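Package: ctewas
Title: Cell-Type-Resolved Epigenome-Wide Association Analysis of Brain Methylomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A tested pipeline for epigenome-wide association studies on
    NeuN-sorted neuronal and glial methylation fractions from postmortem
    cortex. Implements neuron-versus-glia differential methylation calling
    with effect-size and Bonferroni filters, per-cell-type covariate-adjusted
    linear regression of CpG beta values on age and Braak stage, Fisher's
    method meta-analysis across cell types with Benjamini-Hochberg FDR,
    reference-based estimation of neuronal proportions in bulk tissue by
    constrained projection, and a synthetic methylome generator that emulates
    sorted and bulk cohorts with full ground truth for power, calibration and
    recovery analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    limma,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
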