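Package: birdcascade
Title: Cascade Object Detection and Evaluation for Baited Camera-Trap Bird Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Trains and evaluates boosted cascade object detectors
    (Viola-Jones style Haar features and multi-block local binary
    patterns) for counting birds in still frames from baited
    feeding-station camera traps. Provides integral-image feature
    primitives, discrete AdaBoost stage training with per-stage
    false-positive-rate targets and hard-negative mining, multiscale
    sliding-window detection with detection grouping, IoU-based
    matching with precision, recall, F-measure, false-negative-rate
    and false-alarm-rate reports, frame-level summaries, IoU-threshold
    sweeps and region-of-interest crop ablations, plus a deterministic
    synthetic scene generator that emulates the nuisances of field
    imagery (table reflections, cast shadows, occluding seed
    containers, lighting swings, heavy class skew) so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    png,
    jsonlite,
    igraph,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
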