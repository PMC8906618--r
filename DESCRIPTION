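Package: quadgait
Title: Detailed Quadruped Gait Analysis from Motion-Capture Marker
    Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A complete treadmill gait-analysis pipeline for quadrupeds
    (developed for dogs) based on a 25-marker optical motion-capture set:
    reading marker-trajectory exports, linear detrending and zero-lag
    low-pass Butterworth filtering, heel-strike and toe-off detection from
    fore-aft paw-to-girdle distances, gait-cycle segmentation anchored on
    the back-right heel strike, 18 projected joint angles normalized to
    101 points per cycle, 53 scalar gait parameters per cycle (35
    spatio-temporal plus 18 joint ranges of motion), Anderson-Darling
    normality screening, two-sample Kolmogorov-Smirnov condition
    comparisons, RMS joint-curve deviation scores, and automatic per-case
    comparison reports.  Includes a parametric quadruped gait simulator
    (walk, amble, pace, trot) with full ground truth so every pipeline
    stage can be validated without motion-capture hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    jsonlite,
    nortest,
    signal,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
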