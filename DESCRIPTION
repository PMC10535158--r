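Package: deckpipe
Title: Video-Based Counting and Landmarking of Crabs and Lobsters from
    Deck Cameras
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An offline, low-power-oriented computer-vision pipeline for
    electronic monitoring of crustacean fisheries. Converts deck-camera
    video into one record per presented animal: a noisy per-frame presence
    signal is smoothed into single-animal "contigs" by rectangular
    smoothing and step thresholding, a representative frame is selected
    per contig and view, a fixed-size region of interest is cropped
    without resampling, and seven named anatomical keypoints are
    regressed. Ships a seeded synthetic deck-video generator with full
    ground truth (presence signals, views, bounding boxes, keypoints), a
    minimal CNN engine for the reference frame scorer and keypoint
    regressor, a GPS-based record/process scheduler, evaluation metrics
    (contig success rate, pairwise preference accuracy, mean Euclidean
    error), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
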