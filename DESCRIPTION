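Package: somnet
Title: Hippocampo-Thalamo-Cortical Neural-Mass Modelling and Sleep
    Electrophysiology Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic neural-mass firing-rate model of the
    CA3-CA1-cortex-mediodorsal-reticular-reuniens network integrated with a
    fourth-order Runge-Kutta scheme, together with the analysis pipeline used
    to study NREM sleep oscillation coupling: automated Wake/NREM/REM staging,
    detection of slow waves, spindles and sharp-wave ripples, event-locked
    time-frequency analysis, the synchronization-index measure of
    phase-amplitude coupling, circular statistics, spike detection and
    feature-based unit sorting, surrogate-normalized peri-event histograms,
    spike-field phase locking, and quantification of evoked intracellular
    responses. Includes seeded synthetic-data generators with known ground
    truth for every pipeline stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    signal,
    mclust,
    minpack.lm,
    jsonlite,
    data.table,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
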