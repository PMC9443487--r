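Package: spikegate
Title: Spiking Neural Networks with Learned Top-Down Attention Gating
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and direct training of convolutional spiking neural
    networks whose spike-encoding layer is multiplicatively gated by a learned
    top-down attention map. Provides discrete-time leaky integrate-and-fire
    layers with learnable decay and threshold and a rectangular surrogate
    gradient, an analog attention-map generator trained with a weakly
    supervised sparsity/diversity/smoothness objective, backpropagation
    through the unrolled closed loop, L-infinity projected-gradient-descent
    robustness evaluation, firing-rate and multiply-accumulate profiling,
    synthetic scene and event-stream generators, and an address-event binary
    reader for N-MNIST-style recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    tibble,
    dplyr,
    purrr,
    ggplot2,
    generics,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    png,
    jsonlite
Config/testthat/edition: 3
LinkingTo:
    Rcpp,
    RcppArmadillo
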