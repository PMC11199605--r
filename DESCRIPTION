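Package: fogbands
Title: Nonreciprocal Models and Orientation Statistics for Banded Vegetation
    Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis tools for fog-driven banded vegetation
    patterns such as the rootless Tillandsia communities of coastal hyper-arid
    deserts.  Implements a nonlocal interaction-redistribution model with
    anisotropic, nonreciprocal Gaussian influence kernels, its fourth-order
    partial differential equation reduction, closed-form linear stability
    analysis with discrete mode enumeration in finite mixed-boundary boxes,
    Ginzburg-Landau three-mode amplitude equations with equilibrium branches
    and bifurcation diagrams, and a structure-tensor image pipeline that
    measures band orientation fields, slope-direction fields,
    angular-difference histograms and alignment correlations.  A synthetic
    data module generates noisy initial conditions, striped scenes with known
    orientation domains and digital elevation models so the whole pipeline is
    testable without remote-sensing downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    graphics,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    png,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
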