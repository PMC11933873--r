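Package: h2dcos
Title: Cross-Scale Hyperspectral Correlation Spectroscopy and Transfer
    Learning for Leaf SOD Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for predicting superoxide dismutase (SOD) activity of
    plant leaves from paired microscopic and macroscopic hyperspectral
    measurements. Implements generalized two-dimensional correlation
    spectroscopy (2D-COS) in its homogeneous and heterogeneous
    (cross-instrument) forms, including the Hilbert-Noda asynchronous
    transform, slice spectra and sensitive-peak selection; spectral
    pretreatments (Savitzky-Golay smoothing, polynomial baseline removal,
    first derivative); a CNN-LSTM spectral regressor with calibration and
    prediction evaluation; sensitive-wavelength pairing and cross-scale
    model transfer between instruments; pixel-wise activity mapping of
    hyperspectral cubes; black/white reflectance calibration and
    NBT-assay activity arithmetic; and a seeded synthetic paired-modality
    data generator emulating a salt-stress tomato study design so the
    whole pipeline is testable without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    signal,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'h2dcos-package.R'
    'hsi-io.R'
    'nn-core.R'
    'preprocess.R'
    'regressor.R'
    'sod-assay.R'
    'synthetic-data.R'
    'twodcos.R'
    'transfer.R'
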