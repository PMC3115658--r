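Package: cracklelab
Title: Multichannel Lung-Sound Crackle Analysis and Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing crackles (short explosive adventitious lung
    sounds) in multichannel chest-surface recordings. Provides a seeded
    synthetic-recording generator with per-disease crackle profiles
    (interstitial pulmonary fibrosis, congestive heart failure, pneumonia),
    per-channel crackle detection and breath segmentation, half-period
    waveform decomposition and the derived per-crackle features (pitch, T1,
    zero crossings, polarity, duration and amplitude variability), grouping
    of simultaneous ipsilateral detections into crackle families with a
    crackle transmission coefficient and arrival-time source localization,
    per-breath aggregate spatial features, group comparison reports, and
    hierarchical crackle-to-breath-to-patient majority-voting classification
    evaluated by patient-stratified cross-validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    e1071,
    nnet,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
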