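Package: slopentropy
Title: Slope Entropy with Asymmetric Thresholds for Time Series Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Computes Slope Entropy (SlpEn), a symbolic entropy of the
    consecutive-sample gradients of a univariate time series, in its classical
    symmetric form and in two generalisations: independent thresholds for
    positive and negative slopes, and a variant that omits the near-zero tie
    region altogether. Includes the accompanying evaluation machinery for
    two-class signal datasets: single-feature optimal-threshold
    classification, exhaustive grid search over the symbolisation parameters,
    repeated stratified train-validation protocols, seeded generators for
    Gaussian-versus-uniform synthetic benchmarks, plain-text dataset input and
    output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
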