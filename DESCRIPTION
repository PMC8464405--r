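Package: fiberwall
Title: Structure-Informed Constitutive Modeling of the Arterial Wall
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for structure-informed biomechanics of arterial tissue:
    extraction of collagen fiber orientation and dispersion from fibrous-texture
    images by Fourier power-spectrum wedge filtering, bivariate von Mises
    orientation models with closed-form in-plane and out-of-plane dispersion
    parameters, two- and four-fiber-family invariant-based hyperelastic models
    for planar biaxial data, Levenberg-Marquardt parameter estimation with
    non-parametric bootstrap identifiability analysis, cohort-level age-trend
    statistics, and synthetic-data generators for biaxial protocols, fibrous
    texture images, and cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    minpack.lm,
    jsonlite,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
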