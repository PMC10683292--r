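Package: nmrgraph
Title: NMR Chemical Shift Prediction from Small Datasets with
    Message-Passing Graph Networks and HOSE Codes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts per-atom NMR chemical shifts of small organic
    molecules from assigned spectra in MDL SD files.  Provides a
    message-passing graph-network regressor designed for small training
    sets (hundreds to a few thousand molecules), a HOSE-code
    (hierarchically ordered spherical environment) nearest-neighbour
    baseline with sphere fallback and explicit missing-prediction
    semantics, a naive mean-shift reference predictor, and a
    size-stratified evaluation framework (MAE, RMSE, MASE, error
    standard deviation, missing fractions, learning curves,
    solvent-specific subsets).  A synthetic-molecule generator with a
    known local-environment shift rule supports end-to-end testing
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    jsonlite,
    methods,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
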