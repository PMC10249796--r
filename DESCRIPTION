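Package: mfspectra
Title: Wavelet-Based Multifractal Spectrum Analysis of 1D Biomedical Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the multifractal spectrum of one-dimensional intensity
    traces (such as 1H-NMR metabolomics spectra) by the wavelet partition
    function and Legendre transform, reduces each spectrum to six geometric
    descriptors (spectral mode, left/right slopes and tangents, broadness),
    and runs the downstream group-comparison (unbalanced three-way ANOVA) and
    discrimination (PCA plus seven classifiers with repeated stratified
    cross-validation) stages. Includes exact-covariance fractional Gaussian
    noise, binomial multiplicative cascade, and calibrated cohort simulators
    so the whole pipeline can be exercised without real data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    car,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
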