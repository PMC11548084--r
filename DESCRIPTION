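Package: waveden
Title: Wavelet Denoising with a Bayesian-Optimized Bilateral Post-Filter
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Two-stage denoising for single-channel medical images:
    multilevel Daubechies wavelet shrinkage with BayesShrink soft
    thresholding, followed by an exact bilateral edge-preserving filter
    whose three parameters (window diameter, range spread, spatial spread)
    are tuned by Gaussian-process Bayesian optimization with an
    expected-improvement acquisition against a peak signal-to-noise ratio
    objective. Includes an ultrasound-like phantom generator with Gaussian
    and Poisson noise models, PSNR/MSE/SSIM quality metrics, a
    parameter-transfer deployment mode for images without a clean
    reference, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    lhs,
    png,
    stats,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
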