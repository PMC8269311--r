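Package: gravmet
Title: Supernatant Metabolomics of Macrophages in Altered Gravity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for two-platform GC-MS supernatant
    (exometabolome) profiling of primary human macrophages exposed to
    short-term (suborbital rocket) and long-term (space station)
    microgravity. Provides preprocessing of relative-metabolite-abundance
    tables (annotation filtering, detection-limit-aware imputation,
    technical-replicate and volume-weighted compartment averaging,
    missingness filtering, blank subtraction, inter-dataset scaling),
    unsupervised quality control (PCA, heatmap matrices, leakage-outlier
    flagging), two-tier FDR differential analysis with signed fold-change
    semantics, intra-dataset metabolite correlation cluster mining,
    cross-platform quadrant and concordance analysis, and a synthetic-data
    generator with planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
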