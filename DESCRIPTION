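Package: lfqdap
Title: Differential Abundance Analysis for Label-Free Quantitative Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for differential abundance analysis of label-free
    quantification (LFQ) proteomics data from pooled-sample designs with
    technical replicates, as produced by MaxQuant-style protein-group tables.
    Implements peptide-count and quantification filters, log2 transformation,
    two-step normalization (median centring and distribution-width scaling),
    left-censored missing-value imputation anchored at the per-run observed
    minimum, F-test-gated Student/Welch two-sample t-tests against a control
    group, differentially abundant protein (DAP) calling with a fold-change
    cutoff, cross-treatment set intersections, volcano plots on a -log2(p)
    axis, and annotation-grouped abundance heat maps. A synthetic-data
    generator with known ground truth emulates a pooled-plasma
    4-group x 3-technical-replicate design for end-to-end testing and
    power assessment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    grDevices,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
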