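Package: pnsthresh
Title: Peripheral Nerve Stimulation Threshold Modelling for Head Gradient Coils
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing censored peripheral nerve stimulation (PNS)
    threshold measurements from magnetic gradient coil testing. Reads
    per-subject stimulation-threshold tables (with "No PNS" censoring at the
    hardware amplitude limit), expands them into weighted binary stimulation
    observations, fits a weighted logistic dose-response model in rise time,
    gradient amplitude and subject covariates (age, sex, bore Z-offset) by
    iteratively reweighted least squares, and converts the fitted
    coefficients into population threshold curves dG(tau) = dGmin +
    tau * SRmin with covariate-adjusted predictions and Z-offset sensitivity.
    Includes a synthetic-cohort generator that simulates the coarse/fine
    amplitude titration protocol for parameter-recovery studies, and an EPI
    echo-spacing planner that relates gradient amplitude, rise time, hardware
    slew limits and PNS threshold curves to achievable echo spacing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
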