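Package: gmaselect
Title: Motion-Based Video Sequence Selection for Infant General Movement Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Pose-estimator-agnostic toolkit for General Movement Assessment
    (GMA) video triage. Computes a motion-quantity time series from 2D infant
    pose keypoint trajectories (17-keypoint COCO skeleton), selects the K
    highest-motion fixed-duration sequences with a sliding summing window, and
    scores agreement between automatic and expert interval selections using
    interval intersection, dice similarity, maximum dice similarity and
    precision-versus-threshold curves, including leave-one-expert-out and
    inter-rater analyses. Ships a synthetic generator that plants motion
    bursts and simulates jittered expert raters so the whole pipeline can be
    validated against known ground truth.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
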