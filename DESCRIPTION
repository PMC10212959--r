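Package: coughvc
Title: Cough-Sound-Based Estimation and Screening of Vital Capacity
Version: 0.1.0
Authors@R:
    person("coughvc", "maintainers", email = "maintainers@coughvc.dev",
           role = c("aut", "cre"))
Description: Tools to estimate vital capacity from voluntary cough sounds.
    Raw cough recordings are band-pass filtered (140-2000 Hz), a peak
    5-second segment is extracted, and the session sound pressure level
    (SPL, dB re 20 uPa) is computed from microphone voltage. Cough peak
    flow is derived from SPL and age through an exponential flow-sound
    model, and combined with an LMS (lambda-mu-sigma) reference vital
    capacity in a small tanh multilayer perceptron trained under nested
    leave-one-out cross-validation. Includes the full agreement and
    diagnostic-accuracy battery (Bland-Altman with fixed/proportional
    bias tests, Spearman correlation, Friedman/Holm, rank tests, ROC/AUC
    with the DeLong comparison, lower-limit-of-normal screening rates), a
    seeded synthetic cough-cohort generator for end-to-end validation,
    and a command-line pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
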