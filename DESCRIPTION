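Package: shwfsr
Title: Shack-Hartmann Wavefront Sensing Simulation and Large-Dynamic-Range
    Ocular Aberration Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Physical-optics simulation of a Shack-Hartmann wavefront sensor
    for ocular aberrometry, together with the reconstruction methods needed to
    study its dynamic range. Provides Zernike polynomial machinery on the unit
    disk (OSA/ANSI indexing, Noll normalization, analytic gradients), a
    multivariate-Gaussian population model of human-eye aberrations and a
    Kolmogorov-turbulence generator, a Fresnel-propagation Hartmannogram
    simulator driven by configurable sensor geometries, classical centroid plus
    least-squares modal reconstruction, a ConvNeXt-style convolutional
    regressor mapping spot patterns directly to 44 Zernike coefficients, and a
    dynamic-range benchmarking protocol based on single-mode amplitude sweeps
    against a residual-RMS threshold.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    tiff,
    withr,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
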