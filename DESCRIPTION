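Package: skeletrack
Title: Behavioral Phenotyping from Markerless Pose-Estimation Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Post-processing toolkit for keypoint trajectories produced by
    markerless pose-estimation software such as DeepLabCut. Reads
    DLC-format tracking tables, gates low-confidence samples and
    interpolates gaps, reconstructs test arenas in silico from tracked
    landmark points, calibrates pixels to centimeters, and computes
    kinematics (speed, acceleration, distance, zone occupancy, head
    angle). Detects ethological behaviors with rule-based detectors
    (floating in the forced swim test, head dips on the elevated plus
    maze) and with a supervised classifier trained on a position- and
    orientation-invariant skeletal feature representation, evaluated by
    leave-one-video-out cross-validation. Ships a synthetic-session
    generator that emulates a 13-keypoint mouse in open field, elevated
    plus maze and forced swim arenas with scripted ground-truth behavior
    bouts, so the full pipeline is testable without video data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    zoo,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
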