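Package: gmscreen
Title: Movement Analysis of Infant General Movements from Pose Keypoint Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for the quantitative analysis of infant general movements
    (GMs) in the writhing stage from 2D pose-estimation output. Reads
    17-keypoint pose time series (COCO keypoint JSON or CSV), converts them
    into eight joint-angle cosine-similarity signals, summarises each signal
    by its normalized autocorrelation over a lag grid in seconds, and compares
    labelled cohorts (normal versus cramped-synchronized GMs) with per-joint,
    per-lag two-sample t-tests and an omnibus MANOVA. Also implements the
    object keypoint similarity (OKS) metric for scoring keypoint-detection
    accuracy against ground truth, and a synthetic cohort generator with a
    planar forward-kinematic infant skeleton so the full pipeline can be
    exercised and validated without clinical video data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
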