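Package: refdip
Title: Reference-Driven Deep Image Prior Reconstruction for Compressed-Sensing MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-image ("untrained") compressed-sensing MR image reconstruction
    that feeds a previously acquired high-resolution reference image of similar
    anatomy into a Deep Image Prior network instead of random noise, then enforces
    exact k-space data consistency with the acquired measurements. Includes
    centred orthonormal Fourier operators, Cartesian/radial/variable-density
    undersampling mask generators, an hourglass encoder-decoder network with skip
    connections implemented from first principles (convolution kernels in C++),
    relative-error/PSNR/SSIM metrics, a synthetic phantom-pair generator with a
    complex Gaussian measurement-noise model, and a seeded benchmark runner.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    png,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
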