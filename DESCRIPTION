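Package: msnf
Title: Microstate Neurofeedback: Closed-Loop Simulation, Segmentation, and
    Estimation Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for EEG microstate-based neurofeedback. Implements template
    backfitting with absolute spatial correlation, label smoothing and
    short-segment rejection, and the three standard spatio-temporal microstate
    metrics (global explained variance, time coverage, mean duration);
    per-participant calibration of feedback thresholds from epoch-wise target
    state coverage; a real-time feedback loop with time-weighted score smoothing
    and linear gauge scaling; a synthetic EEG generator with Markov microstate
    ground truth and a feedback-responsive virtual subject, so the closed loop
    is testable without hardware; and an estimation-statistics layer with paired
    Cohen's d, BCa bootstrap confidence intervals, sign-flip permutation tests,
    repeated-measures correlation, and noncentral-t power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    patchwork,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    boot,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
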