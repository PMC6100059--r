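Package: seedhsi
Title: Seed Variety Discrimination from Near-Infrared Hyperspectral Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end chemometric pipeline for discriminating seed
    varieties from near-infrared hyperspectral image cubes. Provides
    white/dark reference reflectance calibration, spectral-band cropping,
    maximum-contrast band selection and Otsu segmentation of seeds into
    regions of interest, pixel-wise Daubechies wavelet denoising of
    spectra, principal component score images, effective-wavelength
    selection from loading extrema with proximity deduplication,
    object-wise RBF support vector machine classification with grid
    search, per-seed classification maps, and a synthetic scene generator
    with known ground truth for validating the whole chain at desk scale.
    Cubes are read and written as ENVI-style header plus binary files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    EBImage,
    png,
    stats,
    tools,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
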