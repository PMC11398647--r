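Package: plasticESN
Title: Selective Consistency of Plastic Echo State Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis of selective consistency in recurrent
    reservoir networks with weak Oja-type Hebbian plasticity. Generates
    frozen-noise auditory stimuli for the noise repetition-detection task
    (A-weighted, resampled white noise), simulates sparse tanh echo state
    networks across a spectral-radius sweep, trains a linear readout by
    minibatch gradient descent for one-step-ahead prediction, quantifies
    inter-segment and inter-trial response consistency and prediction error,
    and tests paired Hebbian versus non-Hebbian differences with a sign-flip
    surrogate rank-order test with Bonferroni correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    methods,
    signal,
    stats
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
NeedsCompilation: yes
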