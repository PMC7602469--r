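Package: radarvitals
Title: In-Bed Vital-Sign Monitoring from Multi-Module CW Radar
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Signal-processing pipeline for contactless in-bed monitoring with a
    multi-module 24 GHz continuous-wave Doppler radar. Classifies raw two-channel
    (I/Q) recordings into presence and movement states, reconstructs chest
    displacement in calm sections via direct least-squares ellipse fitting and
    arctangent demodulation, extracts breath-to-breath intervals by zero-crossing
    detection and interbeat intervals by duration-explicit hidden semi-Markov
    heart-sound segmentation, and evaluates results against reference event
    series (interval RMSE, windowed state confusion matrix, Gold-code lag
    synchronization). A ground-truth-labeled scenario simulator emulates the
    bed-radar measurement physics so the whole chain is testable without
    recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
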