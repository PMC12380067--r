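Package: b2bikit
Title: Flexible-Electrode Brain-to-Brain Interface Analysis Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for a brain-to-brain interface built on
    ultraflexible stimulating electrode arrays. Synthesizes labelled
    steady-state visual evoked potential (SSVEP) EEG trials under a joint
    frequency-phase code and decodes them into eight two-mouse commands with
    a dual time/frequency-branch convolutional network; synthesizes
    charge-balanced biphasic stimulation trains; quantifies stimulation-evoked
    turning behavior from 2-D trajectories; computes spike-waveform stability
    metrics; and solves the quasi-static extracellular field around flexible
    and rigid electrode geometries to compare neuron-activation thresholds.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    graphics,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    cluster,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
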