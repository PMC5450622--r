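Package: mansegkit
Title: Headless 3D Neuron Segmentation Sessions and Their Validation Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A scriptable re-implementation of a manual 3D neuron segmentation
    workflow for grayscale confocal or two-photon image stacks. Segmentation
    sessions are driven by replayable action scripts (freehand region drawing
    with automatic closing, click-to-undo of connected regions, split lines,
    pause/resume time accounting) instead of an interactive GUI, so every
    editing behaviour is deterministic and testable. The package also provides
    the quantitative validation suite used to benchmark such segmentations:
    isosurface morphometry (triangle-mesh surface area and volume), the
    gray-level uniformity segmentation-goodness index, 3D topology-preserving
    skeletonization with Sholl analysis and its log-log fit, nearest-point
    matching of segmentations against gold-standard SWC reconstructions with
    separate in-plane and axial distance thresholds, Friedman rank tests for
    inter-rater agreement, and a deterministic synthetic neuron phantom
    generator (tube-rasterized trees with point-spread blur and noise).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tiff,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
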