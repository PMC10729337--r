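Package: predstab
Title: Bootstrap Instability Assessment for Clinical Prediction Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exposes the instability of individual risk predictions from a
    clinical prediction model by replaying the entire model development
    process across bootstrap resamples of the development cohort. Collects
    each individual's multiverse of predicted risks, and computes and
    visualises per-individual mean absolute prediction error (MAPE),
    prediction-instability intervals, the classification instability index,
    and the instability of calibration curves, the c-statistic and net
    benefit. Ships a penalised (lasso) logistic development procedure with
    cross-validated tuning, a pluggable interface for alternative
    procedures, a GUSTO-I-like synthetic cohort generator, and a
    command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    splines,
    stats,
    graphics,
    grDevices,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
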