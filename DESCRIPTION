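Package: stirredCM
Title: Early Prediction of Cardiomyocyte Content in Stirred-Tank hiPSC
    Differentiation Runs
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Data-driven modelling of suspension-bioreactor cardiac
    differentiation of human induced pluripotent stem cells. Engineers
    per-differentiation-day features (means, gradients, second derivatives of
    dissolved oxygen, pH, density-normalised oxygen, cell density, aggregate
    size and nutrient levels) from online and offline bioreactor measurements,
    ranks them by correlation, principal components, random-forest importance,
    Gaussian-process automatic relevance determination and MARS basis usage,
    and trains regression models whose predictions are thresholded at 90
    percent cardiomyocyte content into sufficient/insufficient process classes.
    Evaluation covers leave-one-out, Monte-Carlo and hold-out cross-validation
    with accuracy, precision, recall and the Matthews correlation coefficient.
    A synthetic run generator with planted feature-outcome effects makes every
    stage testable without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    tools,
    utils,
    yaml,
    jsonlite,
    randomForest,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
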