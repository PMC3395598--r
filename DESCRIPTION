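Package: scfluor
Title: Single-Cell Fluorescence Subpopulation and Expression-Noise Analysis
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative single-cell fluorescence analysis for bistable
    gene-expression systems. Provides per-object quantification of grayscale
    micrographs (segmentation, background-subtracted average gray values),
    automated ON-subpopulation estimation from cumulative ranked fluorescence
    distributions via two-segment breakpoint fitting, dual-reporter
    decomposition of expression variability into intrinsic and extrinsic
    noise with bootstrap uncertainty, quadrant-conditioned activation
    analysis, conjugative transfer-frequency computation, and group
    comparison statistics (ANOVA/Tukey with compact letter display). A
    stochastic threshold-activation simulator generates per-cell data,
    paired-reporter samples with analytically known noise components, and
    synthetic images, so the full pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
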