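Package: tonicgl
Title: Tonic Inhibition, Granular-Layer Network Simulation and 3D Gait
    Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools linking cerebellar tonic inhibition to network
    computation and motor coordination. Decomposes tonic GABA-A currents
    from voltage-clamp holding-current traces into pharmacologically
    defined (TTX-sensitive and TTX-insensitive) components, detects
    spontaneous IPSCs, and estimates the extrasynaptic GABA-A reversal
    potential. Simulates a density-faithful, size-scalable spiking model
    of the cerebellar granular layer with stochastic Golgi-cell to
    granule-cell inhibitory synapses and a two-source tonic conductance,
    parameterised for young and adult wild-type and Best1-knockout
    conditions, and analyses the resulting spike trains (Gaussian-kernel
    rate estimation, mossy-fibre to granule-cell correlations, spectral
    power decomposition, bootstrap errors). Quantifies interlimb
    coordination from 9-marker 3D pose trajectories (limb-angle
    correlations, motion segmentation, turning-speed dependence,
    classical gait metrics). Includes seeded synthetic-data generators
    for all three data modalities with ground truth attached.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
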