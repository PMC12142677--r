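Package: cimCCS
Title: Collision Cross Section Calibration, Prediction and Annotation
    Filtering for Cyclic Ion Mobility Spatial Metabolomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Toolkit for collision cross section (CCS) workflows on
    traveling-wave cyclic ion mobility mass spectrometry imaging data.
    Implements exact-mass and adduct m/z arithmetic, the instrument-default
    linear CCS calibration (EDC-corrected drift times) and the multipass
    calibration (Gaussian arrival-time fitting, perturbed periodic drift
    time regression, power-law calibration), per-adduct support-vector
    regression CCS prediction from molecular descriptors, mass spectrometry
    imaging feature-table alignment and differential statistics, and
    CCS-based adjudication and filtering of annotation candidates. A
    simulator generates cyclic ion mobility arrival-time data, feature
    studies and candidate lists with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    e1071,
    minpack.lm,
    jsonlite,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
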