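Package: diffscan
Title: Scanning X-Ray Diffraction Imaging Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of scanning X-ray microdiffraction
    experiments on fibrous biological tissues. Raster scans of 2D area
    detector images are reduced to per-position diffraction ring
    parameters: rings are detected by multiple conical integration and by
    a log-central-difference radial edge operator, merged, and modelled
    with Gaussian radial and centrosymmetric azimuthal profiles to yield
    d-spacings, orientation angles, angular spreads and intensities.
    Results are written as CSV tables and assembled into 2D parameter
    heatmaps with optional multiquadric radial basis function
    interpolation. Includes a seeded generator of synthetic
    fiber-diffraction scans with known ground truth, and a headless
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    jsonlite,
    minpack.lm,
    tiff,
    png
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
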