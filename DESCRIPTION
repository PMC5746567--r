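Package: phageflow
Title: Wall Shear Stress Sensing from a Tethered Brownian Nanorod
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates wall shear stress from time-lapse fluorescence images
    of a wall-tethered Brownian nanorod (e.g. an M13 bacteriophage construct).
    Solves the Stokes-flow resistance and mobility problems for a rigid rod
    near a plane wall with regularized stokeslets and an image system
    enforcing wall no-slip, assembles the rotational advection and diffusion
    coefficients, solves the steady orientation Fokker-Planck equation on the
    hemisphere, and fits the rotational Peclet number to observed in-plane
    rod angles by Kolmogorov-Smirnov distribution matching. Rod angles are
    extracted from images by model-based image analysis: a Gaussian
    point-spread-function forward model of image formation is fitted to each
    frame by staged global optimization. Includes a synthetic-image
    validation harness with Bland-Altman agreement summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    stats,
    tiff
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
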