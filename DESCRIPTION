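Package: stimcorr
Title: Stimulus-Response Correlation Analysis for EEG with CCA, Karhunen-Loeve
    Features and a Correlation-Trained Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how strongly multichannel EEG tracks a
    continuous auditory stimulus envelope. Linear canonical correlation
    analysis reduces the EEG to a single maximally stimulus-correlated
    component, overlapping rectangular windows turn both one-dimensional
    views into fixed-size realizations, a discrete Karhunen-Loeve transform
    (SVD/PCA) truncates each window set to its leading components, and a
    single multilayer perceptron trained with a Pearson-correlation loss maps
    stimulus features to predicted EEG features. Leave-one-trial-out
    cross-testing, per-subject and overall aggregation, and comparison
    reporting against external published columns are included, together with
    a synthetic envelope/EEG generator with a closed-form correlation oracle
    so the whole pipeline is testable without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
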