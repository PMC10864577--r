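Package: specstack
Title: Spectral Feature Engineering and Stacked Regression for Vis-NIR
    Fruit Quality Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and benchmarking feature-engineering
    pipelines that predict fruit soluble solids content (SSC, % Brix)
    from visible/near-infrared (450-1000 nm) reflectance spectra.
    Implements four spectral pre-processors (standard normal variate,
    detrend correction, Savitzky-Golay smoothing, direct orthogonal
    signal correction), nine wavelength-selection methods spanning
    projections (PCA, KPCA, SVD), univariate rankers (F-test, Pearson
    correlation, mutual information) and iterative searches (recursive
    feature elimination, successive projections algorithm, competitive
    adaptive reweighted sampling), SPXY sample-set partitioning,
    ordinary least squares regression evaluated by RMSE, MAPE and RPD
    under five-fold cross-validation, a full orthogonal
    pre-processor-by-selector experiment grid with best-frequency
    tallies, and two-base stacked generalization with out-of-fold meta
    training. A synthetic spectra generator with planted informative
    absorption bands makes every stage of the analysis testable end to
    end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    kernlab,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    MASS,
    mixOmics,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
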