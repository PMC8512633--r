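Package: qrsdetect
Title: R-Peak Detection in ECG Signals via Variational Mode Decomposition and
    Decision-Tree Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects R peaks in single-lead electrocardiogram (ECG) signals.
    The signal is decomposed into narrow-band variational mode functions,
    the Hilbert analytic signal gives per-mode instantaneous frequency and
    energy, and modes whose frequency content lies in the QRS band are
    selected dynamically. Local peaks of the aggregated in-band energy seed
    adaptively sized regions of interest, each summarised by 25 energy,
    frequency and noise features. A majority-vote ensemble of decision trees
    trained on feature subsets classifies regions as R or False-R, and a
    local-maximum search snaps each detection back onto the raw signal.
    Includes WFDB and CSV readers, a synthetic ECG generator with ground
    truth, detection/HRV evaluation metrics, and a batch or sliding-window
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    rpart,
    signal,
    yaml,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
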