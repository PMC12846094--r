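Package: semgfatigue
Title: Muscle Fatigue Classification from Surface Electromyography
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for classifying muscle fatigue levels
    from multi-channel surface electromyography (sEMG) recorded during
    repetitive dynamic exercise. Provides a seeded synthetic cohort
    generator that reproduces the amplitude rise and spectral compression
    of fatiguing muscle, Butterworth band-pass conditioning with linear
    envelope extraction and maximum-voluntary-contraction normalization,
    sliding-window segmentation with a compound task-progress/Borg labeling
    rule, the standard eight time- and frequency-domain EMG features,
    Morlet continuous-wavelet-transform scalogram images with Haralick and
    Hu texture descriptors, classical machine-learning baselines and a
    small convolutional network trained from scratch, and leakage-safe
    leave-one-subject-out evaluation with confusion matrices, ROC and
    precision-recall curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    viridisLite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    png
Config/testthat/edition: 3
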