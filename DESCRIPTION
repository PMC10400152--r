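Package: specspike
Title: Leaf Spectral Libraries, Trait Calibration and Transfer by
    Extra-Weighted Spiking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for calibrating leaf-trait prediction models from
    VIS-NIR-SWIR (350-2500 nm) reflectance spectral libraries and for
    transferring them to external datasets. Provides a spectral-library
    container with wide-CSV input/output, replicate-scan averaging and
    wavelength window binning, partial least-squares regression (PLS1)
    and a relu multilayer-perceptron regressor, 10-fold cross-validated
    hyperparameter selection by RMSE of cross-validation, evaluation by
    R-squared, RMSE, bias and RPD, a PCA domain-shift diagnostic, and
    calibration transfer by extra-weighted spiking (spike-set selection,
    three calibration/testing schemes, spike-size sweeps). A synthetic
    leaf-spectrum generator with trait-linked absorption features and
    controllable domain shift makes every stage testable without
    measured data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
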