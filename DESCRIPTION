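Package: fillstate
Title: Spatial-Extent ("Fill State") Markers for PET Neuroimaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the spatial extent of molecular pathology on PET
    SUV-ratio maps as "fill states": the percentage of voxels inside a
    tracer-specific meta-ROI whose z-score against an amyloid-negative
    cognitively normal control cohort exceeds an abnormality cutoff
    (|z| > 1.65 by default). Provides the full marker-comparison toolkit
    (Kruskal-Wallis staging with post hoc Mann-Whitney tests, paired ROC
    comparison via the DeLong test, covariate-adjusted partial Spearman
    correlations, and multivariate regression with Wilks' lambda term
    tests), a seedable synthetic 3D phantom cohort generator with known
    ground-truth lesion extent, and a compact 3D convolutional network
    that estimates fill states directly from images without a control
    cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    pROC,
    car,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
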