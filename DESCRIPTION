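Package: spontnet
Title: Spontaneous Cortical Network Activity: Event Detection, Correlation
    Dynamics, and a Spiking-Network Model of Interneuron Modulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for spontaneous network activity in the
    developing sensory cortex. Detects spatiotemporal network events in
    wide-field calcium-imaging movies by thresholded 3D connected-component
    labeling, quantifies two-photon population activity with sliding-window
    pairwise Pearson correlations, distance-dependent correlation changes and
    a correlation-matrix squared-distance statistic, extracts patch-clamp
    features (postsynaptic-current kinetics, action-potential waveform,
    ramp excitability, series-resistance quality control), and simulates a
    recurrent excitatory/inhibitory leaky integrate-and-fire network on a 2D
    sheet with distance-dependent connectivity in which a neuropeptide is
    modeled as a resting-potential shift of somatostatin-positive
    interneurons. Seeded synthetic-data generators with known ground truth
    stand in for raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
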