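Package: adsnet
Title: Robust Spiking Neural Networks by Distillation from Rate Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Supervised training of spiking neural networks for robust
    deployment on mixed-signal neuromorphic hardware. A non-spiking tanh
    rate network is trained on a temporal task by backpropagation through
    time, then a network of leaky integrate-and-fire neurons (an
    "arbitrary dynamical system" network) learns to mimic the rate
    network's internal dynamics using a local error-feedback learning rule
    built on the efficient balanced network spike-coding scheme. Includes
    task generators (temporal XOR, Butterworth filterbank audio features
    with a synthetic keyword fixture), forward-Euler simulation
    primitives, and a robustness-evaluation harness covering simulated
    analog device mismatch, post-training weight quantisation, thermal
    noise and sudden neuron silencing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    jsonlite,
    yaml,
    car,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
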