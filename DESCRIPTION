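Package: pmwave
Title: Dynamic Sparse-Grid Wavelet Collocation for Perona-Malik Image Denoising
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Edge-preserving denoising of grayscale images by solving the
    Perona-Malik anisotropic diffusion equation with an interpolating-wavelet
    multilevel collocation method on adaptive sparse grids. Interval bases are
    built by Lagrange or Newton divided-difference extrapolation to external
    collocation points, with the number of external points chosen dynamically
    from the decay of divided differences under a condition-number growth cap.
    Time integration uses a homotopy-perturbation predictor-corrector
    (explicit Euler predictor, trapezoidal corrector) with wavelet-coefficient
    refresh and magnitude thresholding each step. Images may be partitioned
    into even blocks solved independently, with per-block condition monitoring
    and seam diagnostics. Includes Shannon, Shannon-Gabor and
    Daubechies-autocorrelation (Deslauriers-Dubuc) bases, a finite-difference
    reference solver, a seeded synthetic phantom generator, and PNG/TIFF/PGM
    input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    grDevices,
    graphics,
    png,
    stats,
    tiff,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
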