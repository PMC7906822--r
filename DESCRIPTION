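Package: miattn
Title: Motor-Imagery EEG Decoding with an Attention-Fused CNN-BiLSTM Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end decoding of four-class motor-imagery EEG (left hand,
    right hand, foot, tongue) in the BCI Competition IV 2a layout. Provides a
    synthetic session generator with class-dependent mu/beta event-related
    desynchronization, trial epoching and windowing, per-window
    standardization, tied-weight autoencoder training-set expansion, a shallow
    convolutional network serially fused with a bidirectional LSTM through
    softmax attention pooling, minibatch Adam training, and a full evaluation
    suite (one-vs-rest confusion metrics, Cohen's kappa against chance 1/C,
    per-subject summaries). The network and its backpropagation are
    implemented natively in R.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    arrow,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
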