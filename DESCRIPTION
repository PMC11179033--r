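Package: cogema
Title: High-Frequency Wearable Assessment of Cognition, Mood, and Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for high-frequency ecological momentary
    assessment (EMA) studies that combine brief wearable cognitive testing
    (2-back working-memory sessions scored as bounded d-prime), short daily
    mood questionnaires, and passively recorded step counts and heart rate.
    Provides a synthetic cohort generator with known ground truth; signal
    detection scoring with a log-linear extreme-rate correction; data
    cleaning rules (study onset harmonization, non-wear day flagging,
    sparse-hour exclusion); hierarchical polynomial trend models with
    continuous-time AR(1) or daily AR(1) residual correlation fitted by
    maximum likelihood and selected by sequential likelihood-ratio tests;
    diurnal and day-of-week fixed effects; individual inverse-curve learning
    trajectories with 90 percent learning rates and stable maxima; and
    concurrent and time-lagged covariation of within-person residual
    fluctuations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    nlme,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
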