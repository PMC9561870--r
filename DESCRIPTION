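Package: obstress
Title: Marker-Gated Transcriptomic Analysis of Osteoblast Stress Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects dose-dependent stress-gene responses in osteoblasts
    from single-cell, spatial and bulk RNA-seq count data using
    marker-threshold cell gating, relative (percent-of-total-UMI)
    normalization, UMI-weighted pseudobulk differential expression with a
    Wilcoxon/Bonferroni significance rule, covariate-sorted running-average
    trajectory analysis with false-positive accounting, spatial-spot
    selection by inclusion/exclusion marker thresholds, and
    housekeeping-gene relative-quantity normalization of bulk libraries.
    Ships a negative-binomial synthetic-data generator with known ground
    truth so every stage of the pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
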