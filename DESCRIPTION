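Package: NIRcal
Title: Near-Infrared Calibration Workflow for Protein Content in Ground Grain
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Chemometric calibration of protein content from near-infrared
    reflectance spectra of ground grain. Implements eight spectral
    preprocessing variants (Savitzky-Golay smoothing, multiplicative scatter
    correction, standard normal variate, first derivative and their
    combinations), wavelength selection by the successive projections
    algorithm (SPA) and uninformative variable elimination (UVE), regression
    by NIPALS partial least squares, epsilon-support-vector regression and
    extreme learning machines, concentration-gradient calibration/prediction
    partitioning, and R/RMSE/RPD model evaluation. Ships a synthetic spectra
    generator with known composition for end-to-end parameter-recovery
    testing when raw instrument data are unavailable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    signal,
    e1071,
    MASS
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'synthetic.R'
    'io.R'
    'preprocess.R'
    'models.R'
    'selection.R'
    'evaluation.R'
    'pipeline.R'
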