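Package: erpoverlap
Title: Simulation and Analysis of Response-Related Contamination in Stimulus-Locked ERPs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how response-related EEG components (the P3 and
    motor-related potentials) distort stimulus-locked event-related potentials
    such as the N400 in speeded-response semantic-priming designs. Provides a
    component-based synthetic EEG generator with ground truth, a standard ERP
    preprocessing chain (zero-phase Butterworth band-pass filtering,
    resampling, EOG regression, epoching, baseline correction), trial binning
    and stimulus-/response-locked averaging, single-trial P3-latency
    estimation by iterative Woody template matching, construction of
    latency/RT-matched trial groups, and linear mixed-effects analyses with
    by-subject slopes and by-item intercepts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    lme4,
    lmerTest,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
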