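Package: leafspec
Title: Visible/Near-Infrared Leaf Chemometrics: Preprocessing, Wavelength
    Selection and Calibration Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A chemometric workflow for calibrating visible/near-infrared
    (400-1000 nm) diffuse reflectance spectra of leafy produce against
    laboratory quality indicators (soluble solids content, moisture content,
    vitamin C). Implements reflectance calibration from raw instrument
    counts, seven classical spectral preprocessing transforms, Kennard-Stone
    sample partitioning, three characteristic-wavelength selectors (CARS,
    UVE, SPA), three calibration models (PLSR, MLR, LS-SVM), the standard
    RC/RMSE/RPD evaluation metrics, and a synthetic leaf-spectrum generator
    with known ground truth for testing and method study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    MASS,
    signal,
    stats,
    utils,
    yaml
Suggests:
    mixOmics,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
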