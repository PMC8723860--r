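Package: ckdens
Title: Ensemble Deep Learning Decision Support for Chronic Kidney Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Diagnose chronic kidney disease from tabular clinical records
    with an ensemble of three classifiers: a kernel extreme learning machine
    solved in closed form, a deep belief network of stacked restricted
    Boltzmann machines pretrained by contrastive divergence, and a hybrid
    one-dimensional convolutional network with gated recurrent units.
    Includes adaptive synthetic (ADASYN) minority oversampling for class
    rebalancing, quasi-oppositional butterfly optimization for
    hyperparameter tuning, leakage-free preprocessing of mixed
    numeric/categorical data with missing values (CSV and ARFF input), a
    seeded synthetic-data generator emulating the chronic-kidney-disease
    schema, and a multi-run evaluation protocol reporting sensitivity,
    specificity, accuracy, F-score, Cohen's kappa and ROC AUC.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    foreign,
    pROC,
    withr,
    nnet,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    caret,
    yaml,
    jsonlite
Config/testthat/edition: 3
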