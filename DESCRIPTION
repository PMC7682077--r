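Package: hspdual
Title: Dual-Function Characterization of Heat Shock Proteins Across Tumor and
    Normal Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pan-cancer characterization of the heat shock protein (HSP) gene
    family across paired tumor/normal expression cohorts: per-cohort Spearman
    co-expression networks with a size-matched resampling null for network
    disruption, differential expression with family-level tallies, survival and
    clinical-group associations, proliferation-marker (MKI67) correlation,
    dependency-screen background comparison, a formula-defined EMT score with a
    weighted Kolmogorov-Smirnov GSEA engine for median-split phenotypes, and
    dual-function quadrant classification of genes that simultaneously promote
    one cancer hallmark while suppressing another. Includes a synthetic cohort
    generator with planted, recoverable structure so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
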