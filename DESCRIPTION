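Package: dissmap
Title: Dissolution Profile Prediction from Raman and NIR Chemical Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for predicting the in vitro
    dissolution profile of hydroxypropyl methylcellulose (HPMC) matrix
    sustained-release tablets from hyperspectral chemical images. Provides a
    synthetic-data generator for Raman and near-infrared (NIR) maps of
    five-component tablets, spectral preprocessing (Savitzky-Golay smoothing
    and derivatives, asymmetric-least-squares Whittaker baseline correction,
    normalization), classical least squares (CLS) unmixing into concentration
    maps, a small convolutional neural network that regresses HPMC particle
    size from a concentration map, and a single-hidden-layer feedforward
    network trained with Bayesian-regularized Levenberg-Marquardt that maps
    (mean HPMC concentration, particle size) to a 37-point dissolution
    profile. Profiles are compared with the f2 similarity factor (with the
    85 percent truncation rule), RMSE and R squared.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
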