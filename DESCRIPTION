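Package: graspdecode
Title: Decoding Hand-Grasp Kinematics from Low-Frequency Scalp EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An offline analysis pipeline for decoding continuous hand-grasp
    kinematics (joint angular velocities and their principal-component
    synergies) from low-frequency (0.3-1 Hz) scalp EEG. Implements the
    signal-conditioning chain (zero-phase Butterworth filtering, channel
    exclusion, downsampling, differentiation, temporal lag embedding, trial
    segmentation, feature standardization), kinematic synergy extraction by
    PCA, a lagged linear (Wiener) decoder with stratified cross-validation,
    channel ranking and per-lag contribution statistics, empirical chance
    levels from phase-scrambled and trial-scrambled surrogates, and a
    five-class grasp classifier built on simplex-weighted multiple-kernel
    learning (SimpleMKL) with a mutual-information timeline. A synthetic-data
    generator produces EEG/kinematics recordings with the lagged linear
    coupling and low-rank synergy structure the analysis assumes, so every
    stage is testable without access to human recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    kernlab,
    minpack.lm,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
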