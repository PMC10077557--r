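Package: uvabc
Title: Classification of UV-Vis Spectra with a Bee-Colony-Optimised
    Neural Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for classifying ultraviolet absorption spectra of sodium
    chloride, sodium hydroxide, beta-phenylethylamine (PEA) and their
    mixtures.  Implements the artificial bee colony (ABC) optimiser and an
    improved adaptive variant (IAABC) that adds a cycle-decaying inertia
    weight and a Levy-flight mutation step, and couples it to a small
    feed-forward neural network (tansig hidden layer, logsig output)
    trained on principal-component scores of the spectra.  Includes a
    synthetic Beer-Lambert spectrum generator with Gaussian absorption
    bands, PCA feature extraction, a full evaluation-metric suite
    (confusion matrix, recall, precision, F-score, accuracy, RMSEP, REP,
    R squared) and a small command line interface for the end-to-end
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
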