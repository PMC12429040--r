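Package: trackmorph
Title: Cell Tracking, Morphometry and Autocorrelation-Corrected Statistics
    for Time-Lapse Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A detection-agnostic multi-object cell tracker for time-lapse
    microscopy built on cost-matrix assignment (appearance, shape and spatial
    proximity) with adaptive gating, split/merge recovery, re-identification
    of occluded tracks and lineage bookkeeping; a static and dynamic
    morphometric feature suite (projected area, circularity, ellipse
    elongation and orientation, solidity, Hu moments, and twelve trajectory
    motility metrics including mean squared displacement, directional
    persistence and arrest coefficient); and a non-parametric statistics
    engine for comparing experimental series of autocorrelated frame metrics:
    moving-average smoothing, Bartlett effective-sample-size corrected and
    permutation Friedman tests over sliding windows, Conover-Holm post hoc
    comparisons, bootstrap confidence intervals and distributional distances.
    Includes a synthetic scene generator (motion models, divisions, detection
    dropouts, grouped AR(1) metric panels) providing ground truth for
    validation, and a staged command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    polyclip,
    clue,
    zoo,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    EBImage,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: CellBiology, Visualization, TimeCourse, StatisticalMethod
RoxygenNote: 7.3.3
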