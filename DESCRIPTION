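Package: megpac
Title: Cross-Regional Phase-Amplitude Coupling Analysis for MEG
    Treatment-Response Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying cross-regional alpha-gamma phase-amplitude
    coupling (PAC) in epoched magnetoencephalography recordings of emotional
    face processing, and its relation to antidepressant treatment response.
    Provides a synthetic-cohort generator with injected coupling and linked
    clinical outcomes, zero-phase notch/band-pass filtering with
    variance-based trial and channel rejection, a linearly constrained
    minimum variance (LCMV) beamformer on toy source grids with symmetric
    orthogonalization for leakage control, Hanning and Slepian multitaper
    time-frequency estimation, phasor-envelope coherence comodulograms,
    cluster-based permutation tests with FDR-corrected pointwise statistics,
    and ROC-based prediction of treatment response from coupling features.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'megpac-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'utils.R'
    'cfc.R'
    'group_stats.R'
    'response_prediction.R'
    'spectral.R'
    'source_recon.R'
    'preprocess.R'
    'simulate.R'
    'pipeline.R'
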