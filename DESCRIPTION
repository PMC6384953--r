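Package: bfgamma
Title: Gamma-Burst Detection and Spike-Field Coupling Analysis for
    Optogenetic Basal Forebrain Recordings
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing extracellular recordings from optogenetic
    experiments in the rostral basal forebrain: envelope-threshold detection
    of transient gamma-band (20-80 Hz) oscillatory events in the local field
    potential with Morlet-wavelet characterization, classification of single
    units by their photostimulation response (peri-event histograms and the
    sliding-sweeps permutation test), spike-field coupling statistics
    (event-triggered correlograms with shuffle nulls, pairwise phase
    consistency spectra, single-unit versus multi-unit multitaper coherence),
    multitaper power spectra with 1/f normalization and laser on/off
    comparisons under FDR control, and behavioral scoring (open-field
    locomotor speed, Y-maze spontaneous alternation). Ships a synthetic
    session generator with ground-truth labels so the full pipeline is
    testable without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
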