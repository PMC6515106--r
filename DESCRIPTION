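Package: cyclephase
Title: Smart Annotation of Cycle Phases in Wearable Sensor Recordings
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for semi-automatic (smart) annotation of cyclic human
    activities recorded with shoe-mounted inertial sensors and pressure
    insoles. Provides a synthetic per-foot signal generator with ground-truth
    labels, pressure edge detection of stance onsets and ends, a semi-
    supervised hierarchical hidden Markov model with iterative batch training
    and task-restricted Viterbi decoding, unsupervised cycle detectors (peak
    detection and local cyclicity estimation), label post-processing rules,
    and event-based evaluation metrics (F1, miss rate, false discovery rate,
    labeling effort) with a 50 ms matching tolerance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
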