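Package: serialq
Title: Latency-Resolved fMRI Analysis of Dual-Task Serial Queuing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis tools for latency-resolved (ultrafast TR)
    fMRI studies of dual-task interference and the psychological refractory
    period. Provides a synthetic-data generator with a central-bottleneck
    reaction-time model and region-specific neural event rules, a double-gamma
    hemodynamic response model with condition-specific parameter fitting,
    percent-signal scaling and prewhitened GLM estimation with shape-free
    (FIR) and trial-wise (least-squares-sum) deconvolution, time-resolved
    multivoxel pattern decoding with onset and peak latency estimation,
    quartile reaction-time diagnostics separating response-selection from
    response-execution BOLD profiles, multi-trial vector-autoregressive
    Granger causality, and the group-level inferential helpers used
    throughout (paired t, repeated-measures ANOVA, Pearson correlation,
    Benjamini-Hochberg FDR, and a JZS Bayes factor).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    RNifti
Suggests: testthat (>= 3.0.0), glmnet, yaml, MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
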