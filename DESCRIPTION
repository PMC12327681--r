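Package: msmce
Title: Multi-Channel Embedding Representations for Raw Mass Spectrometry Classification
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for classifying raw mass spectrometry runs without classical
    peak-picking preprocessing. Implements the MSMCE multi-channel embedding
    representation module (a fully connected encoder followed by cascaded 1-D
    convolutions whose output channels are concatenated with the global
    embedding), the surrounding data-processing workflow (TIC filtering, m/z
    binning, retention-time window aggregation, TIC normalization), small
    trainable 1-D CNN, LSTM and transformer classification heads with a shared
    reverse-mode automatic-differentiation engine, a stratified training
    protocol with Adam, learning-rate plateau decay and early stopping, exact
    paired Wilcoxon signed-rank testing and bootstrap confidence intervals for
    fold-wise model comparison, analytic MACs/parameter profiling, a synthetic
    labelled-spectrum generator, and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
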