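Package: faceloop
Title: Closed-Loop Emotional Face Neurofeedback: Simulation and Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates real-time fMRI neurofeedback experiments in which the
    valence of a morphing emotional face is coupled to the participant's
    amygdala BOLD signal, and provides the complete offline analysis chain.
    Includes a four-region (V1, FFA, amygdala, mOFC) bilinear neural model
    with canonical-HRF observation, the causal per-volume online signal
    chain (Kalman de-spiking, expanding-window detrending, AR(1)
    prewhitening, adaptive dynamic-range scaling), the circularity-aware
    offline GLM with orthogonalized regressors, block-wise amygdala betas
    and within-run habituation slopes, run-by-group linear mixed-effects
    inference, and a reduced bilinear dynamic causal modelling pipeline with
    Bayesian model averaging over a 128-model space.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    minpack.lm,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
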