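Package: seqrisk
Title: Temporal EHR Sequence Risk Models with Perturbation-Based
    Feature Contribution Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds case/control cohorts from longitudinal electronic
    medical records, encodes dated diagnosis, medication and abnormal
    laboratory events into integer-indexed visit sequences, and fits
    time-aware LSTM (TLSTM), reverse-time attention (RETAIN) and
    logistic-regression classifiers for near-term risk prediction.
    Includes extraction of psychotherapy status from clinical notes via
    keyword and sentence-embedding similarity, social-determinant-of-health
    covariate coding, and a perturbation-based relative-contribution
    analysis that ranks risk and protective features using median-ratio
    contributions, Wilcoxon rank-sum tests and Benjamini-Hochberg false
    discovery rate control. A seeded synthetic-cohort simulator with
    planted risk and protective effects supports end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
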