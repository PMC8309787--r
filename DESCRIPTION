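Package: peartrack
Title: Tracking-by-Detection Counting of Orchard Fruit from Per-Frame
    Detection Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A detector-agnostic toolkit for counting fruit in orchard
    video from per-frame bounding-box detection streams. Implements an
    online multi-object tracker (constant-velocity Kalman filtering,
    Mahalanobis-gated motion and appearance association solved by the
    Hungarian algorithm, and a tentative/confirmed/deleted track
    lifecycle), two counting strategies over tracker output (horizontal
    ROI-line crossing and unique track-ID counting, plus a
    lifespan-coverage filtered variant), Pascal-VOC style detection
    evaluation (11-point interpolated average precision, IoU-thresholded
    precision/recall), CLEAR-MOT style counting evaluation, readers and
    writers for MOT-challenge and YOLO/Darknet text dialects, a synthetic
    orchard-pass simulator for end-to-end benchmarking without video
    data, and training-methodology utilities (multi-step learning-rate
    schedules with linear warmup, stratified four-way data splitting,
    IoU-distance k-means anchor clustering).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
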