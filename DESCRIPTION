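Package: herdtrack
Title: Multi-Object Tracking and Evaluation for Livestock Surveillance Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detector-agnostic multi-object tracking of cattle (and other
    livestock) from per-frame bounding-box detections. Implements a
    light-weight geometry-based tracker built on location and aspect-ratio
    step distances with periodic re-matching of lost identities, a
    SORT-family Kalman-filter tracker with a bounded appearance gallery and
    a Tentative/Confirmed/Deleted track lifecycle, a 128-dimensional
    appearance embedding stage with an unsupervised identity-splitting
    procedure for building re-identification datasets, CLEAR multi-object
    tracking metrics (MOTA, identity switches, fragmentations) and
    detection metrics (precision, recall, F1, average precision), readers
    and writers for MOT-Challenge and YOLO text formats, and a synthetic
    herd simulator that generates ground-truth trajectories and corrupted
    detections for benchmarking trackers without farm video.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    png,
    EBImage,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
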