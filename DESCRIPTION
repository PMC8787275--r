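Package: fractalbold
Title: Fractal Scaling Analysis of fMRI BOLD Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the spectral index and extended Hurst exponent of
    fMRI BOLD time series from the Welch power spectral density, classifies
    signals as fractional Gaussian noise or fractional Brownian motion, and
    carries the estimates through a full cross-condition pipeline: voxelwise
    Hurst, ALFF and temporal-SD maps, framewise-displacement quality control
    with motion-matched cohort construction, network ROI paired statistics
    with Holm correction, ICC(2,1) test-retest reliability with bootstrap
    confidence intervals, and audiovisual stimulus feature extraction.
    Includes a synthetic phantom generator so every stage is verifiable
    without access to scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
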