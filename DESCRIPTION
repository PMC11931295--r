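Package: burnchrom
Title: Burn-Severity Imaging from RGB Photographs via Hemoglobin Chromophore Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Estimates skin chromophore concentrations (oxygenated, deoxygenated
    and methemoglobin, and melanin) from RGB color images and classifies burn
    severity from the derived hemoglobin parameters. A two-layer white Monte
    Carlo model of photon transport in skin generates diffuse-reflectance
    spectra, which are integrated to CIEXYZ tristimulus values and used to fit
    a quadratic regression inverse mapping XYZ to chromophore concentrations.
    Total hemoglobin, tissue oxygen saturation and methemoglobin saturation
    maps feed a canonical discriminant analysis that classifies image pixels
    into severity classes, with leave-one-out cross-validation and
    one-vs-rest ROC/AUC evaluation. Includes synthetic-data generators for
    in-silico validation, phantom images and study-structured feature tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    pROC,
    png
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
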