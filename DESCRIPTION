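Package: ripplemap
Title: Place-Field Coding, Oscillation and Reactivation Analysis for CA1 Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for hippocampal CA1 tetrode
    sessions: occupancy-normalized place-field rate maps with Skaggs spatial
    information, sparsity and coherence place-cell criteria; Bayesian position
    decoding from population vectors under a Poisson spiking model; noise and
    speed-compensated partial correlations of instantaneous firing-rate
    counts; theta, gamma and sharp-wave-ripple epoch detection from the local
    field potential; spike-phase circular statistics (mean vectors, Rayleigh,
    Watson-Williams and angular-variance ratio tests); and exploration-to-sleep
    reactivation via cofiring similarity. A synthetic session generator with
    known ground truth (foraging trajectories, inhomogeneous-Poisson place
    cells, composite LFP with sleep structure) makes every stage testable by
    parameter recovery without animal data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
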