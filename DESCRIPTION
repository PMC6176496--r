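Package: mmnnet
Title: Source-Space Phase-Lag Connectivity Networks for the Auditory
    Mismatch Negativity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for studying which cortical areas
    support the auditory mismatch negativity (MMN) through long-range
    phase synchronization.  Implements oddball ERP preprocessing
    (band-pass filtering, epoching, baseline correction, artifact
    rejection, deviant selection, MMN difference waves), a weighted
    minimum-norm inverse onto a 148-region cortical parcellation,
    trial-wise gamma-band weighted phase lag index (wPLI) connectivity
    over a peak-centered 100 ms window, density-thresholded brain
    networks with long/short-distance connection statistics over 14
    cortical areas, and paired group comparisons across stimulus
    conditions and consciousness states.  A synthetic-data module
    generates oddball stimulus sequences and coupled-oscillator EEG/ROI
    signals with known ground truth so every stage is testable without
    human recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    jsonlite,
    signal,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
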