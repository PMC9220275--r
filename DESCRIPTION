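Package: abcsex
Title: Adjusted Binary Classification for Osteometric Sex Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reject-option binary sex classification from skeletal measurements.
    Provides four linear posterior-probability classifiers (logistic regression,
    linear discriminant analysis, componentwise boosted GLM, linear support
    vector machine with sigmoid calibration), Monte-Carlo (leave-group-out)
    cross-validation, ROC-based univariate ranking and recursive feature
    elimination, and the adjusted binary classification (ABC) threshold search
    that moves the per-sex posterior-probability cutoffs outward until accuracy,
    PPV and NPV on the classified subset reach a target level, leaving the
    remainder indeterminate. Includes a synthetic femoral-cohort generator with
    published per-sex Gaussian marginals, a training-sample-size sweep, and
    report rendering for the full protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    kernlab,
    jsonlite,
    yaml
Suggests:
    MASS,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
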