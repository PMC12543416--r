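Package: cagetrack
Title: Dual-View Home-Cage Rodent Tracking and Circadian Behavior Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Evaluates synchronized per-frame detection streams from two
    orthogonal infrared cameras watching a rodent home cage. Fuses front and
    side bounding-box midpoints into 3D positions, classifies each frame as
    house, wheel or outside occupancy, accumulates region times, locomotion
    distance and running speed, and aggregates the metrics over circadian
    phase windows such as the food-anticipatory activity period. Ships a
    seeded cage simulator (Markov dwell model, dual-view projection,
    detection corruption, frame rendering) and a threshold-plus-connected-
    components blob detector so the full pipeline can be validated
    end-to-end without real video.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    jsonlite,
    yaml,
    zoo,
    EBImage,
    png,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
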