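Package: indentfe
Title: Inverse Finite-Element Characterization of Abdominal Soft Tissue from
    Macro-Indentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processes in vivo macro-indenter measurements of human abdominal
    soft tissue into region-mean reference curves and identifies first-order
    Ogden hyperelastic material parameters by inverse finite-element analysis.
    Includes polynomial force-displacement curve fitting, reconstruction of
    skin surface-displacement profiles from tilted 8x8 time-of-flight distance
    sensors, surface-EMG envelope quantification with MVC normalization, an
    axisymmetric large-deformation finite-element forward model of rigid
    frictionless hemispherical indentation into a nearly incompressible Ogden
    cylinder, a grid-search inverse identification minimizing a combined
    force/surface objective, and generators for fully synthetic experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
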