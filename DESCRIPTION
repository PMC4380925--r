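Package: morphloc
Title: Single-Cell Morphometry and Transcription-Factor Localization Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relating single-cell morphology to NF-kB
    nuclear translocation in high-content imaging screens. Provides a
    synthetic two-channel scene and single-cell data generator with known
    ground truth; watershed/propagation segmentation of nucleus, cell body,
    membrane band and perinuclear ring with a 77-feature shape, context and
    intensity catalog including the nuclear/perinuclear NF-kB ratio;
    well-level profiling with PCA and centered-correlation centroid-linkage
    clustering of cell lines; discriminative feature selection; per-line
    Bayesian network dependency inference (BDeu-scored hill climbing with
    bootstrap edge confidence); a three-predictor multilinear shape-response
    regression of NF-kB fold changes with tenfold cross-validation and
    prediction-interval outlier flagging; and Morlet continuous-wavelet
    analysis of damped translocation oscillations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    ape,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
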