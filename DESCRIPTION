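Package: mraxon
Title: Effective MR Axon Radius Mapping from Strong-Gradient Diffusion MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of the effective MR axon radius from spherically
    averaged diffusion MRI signals acquired at strong diffusion weighting
    (b >= 6 ms/um^2). Implements the Gaussian-phase (van Gelderen) forward
    model of restricted diffusion inside a cylinder, a two-shell estimator
    of the nuisance amplitude and effective radius with Cramer-Rao precision
    bounds and protocol optimisation utilities, Rician maximum-likelihood
    spherical-mean estimation, diffusion kurtosis fitting, an along-tract
    segment-averaging pipeline for fiber bundles, test-retest reliability
    statistics (test-retest variability, intraclass correlation,
    Bland-Altman, correlation matrices, power analysis), and a synthetic
    data generator emulating a strong-gradient human protocol with known
    ground truth.
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
    pracma,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
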