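Package: caephys
Title: Bimodal Analysis of Simultaneous Calcium Imaging and Tetrode
    Electrophysiology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for joint analysis of two-photon calcium imaging
    (per-ROI dF/F traces) and multi-electrode extracellular recordings
    acquired simultaneously through a GRIN-lens/tetrode implant. Provides
    a synthetic session generator with known ground-truth coupling,
    frame-trigger and behavioral-video synchronization, Morlet wavelet
    band-power extraction of the local field potential, ROI-by-electrode
    band-power Pearson correlation with circular-shift permutation nulls
    and Benjamini-Hochberg significant fractions, spike-train to calcium
    matching by exponential-kernel convolution, occupancy-normalized
    spatial activity maps with two-dimensional Kolmogorov-Smirnov
    comparisons, and optical quality-control procedures (magnification,
    field of view, lateral and axial resolution) on calibration images.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    signal,
    minpack.lm,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), tiff, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'caephys-package.R'
    'synthetic-session.R'
    'synthetic-images.R'
    'signal-io.R'
    'lfp-power.R'
    'correlation.R'
    'spike-match.R'
    'spatial-maps.R'
    'optics-qc.R'
    'pipeline.R'
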