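Package: emgrasp
Title: Decoding Upcoming Grasp Gestures from Dynamic Surface EMG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end framework for decoding the upcoming grasp gesture from
    multichannel surface electromyography (EMG) recorded during natural
    reach-to-grasp movements. Provides a protocol-faithful synthetic EMG
    generator, band-pass and envelope preprocessing with per-muscle maximum
    voluntary contraction (MVC) normalization, unsupervised segmentation of
    each trial into reaching/grasping/returning/resting phases by greedy
    Gaussian segmentation (with an exact dynamic-programming oracle),
    sliding-window time-domain features (RMS, MAV, VAR), a 14-class
    extremely-randomized-trees gesture classifier trained under three
    phase-selection strategies, and a grasp-onset-aligned real-time style
    evaluation producing probability/accuracy curves, the intersection time
    t_i and the probability margin d_p.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    ranger,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
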