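Package: powderlaw
Title: Power-Law Analysis of Powder-Averaged Diffusion MRI Signals under
    Axisymmetric b-Tensor Encoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-form powder-averaged (direction-averaged) diffusion MRI
    signals for arbitrary axisymmetric b-tensor encodings (linear, planar,
    spherical and everything between), the high-b asymptotic expansion of the
    planar-encoding stick signal, and a classifier for the conditions under
    which the direction-averaged signal follows a power law S = beta * b^-alpha.
    Includes a three-compartment Watson-dispersed tissue simulator (cylinders
    with Gaussian-phase-approximation radii, Gaussian extra-axonal compartment,
    restricted sphere / dot compartment) with Rician noise, multi-shell
    protocol construction with electrostatic-repulsion direction schemes,
    NIfTI/bval/bvec/bdelta dataset I/O, and the downstream analyses: power-law
    fitting with BIC, Rayleigh-background noise estimation, rectified
    noise-floor limits on b*D per encoding shape, minimum direction counts for
    rotationally invariant powder averages, and dot/sphere-fraction
    sensitivity sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    RNifti,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
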