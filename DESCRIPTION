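Package: eegcnn
Title: Multi-Channel Convolutional Networks for EEG Band-Power Mental-Task Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classification of mental tasks (left-hand motor imagery, right-hand
    motor imagery, word generation) from precomputed EEG power-spectral-density
    features: 8 centro-parietal electrodes times 12 frequency sub-bands (8-30 Hz
    at 2 Hz resolution) sampled 16 times per second. Implements a channel-isolated
    convolutional network that slices each 96-channel window into independent
    per-channel streams (two stacked 1-D convolutions, pair-max feature-map
    pooling, ReLU) joined only at the fully connected head, together with its
    training stack (MSRA initialization, softmax cross-entropy with exact
    backpropagation, AdaGrad and momentum SGD, five learning-rate schedules),
    a one-factor hyperparameter scan with ceiling rounding, a one-vs-rest
    multi-class ROC evaluation suite (overall success rate, ACC/TPR/TNR/PPV/NPV,
    generalization error), a synthetic PSD session generator for end-to-end
    testing, and file I/O for whitespace-delimited feature files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
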