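Package: wmsdscreen
Title: Weighted Mean Squared Deviation Feature Screening for Binary Data
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Marginal feature screening for binary classification with
    ultrahigh-dimensional binary features using the weighted mean squared
    deviation (WMSD) statistic, together with Chi-square and mutual-information
    screeners for comparison. The number of retained features is chosen by a
    Pearson-correlation rule that locates the window of the rank-ordered score
    sequence best fitting a power law on doubly logarithmic axes. Includes a
    multivariate Bernoulli simulator with a known relevant feature set,
    selection error rates, Bernoulli naive Bayes and ridge-stabilised logistic
    classifiers, AUC, and an experiment driver for screening studies on
    simulated or user-supplied binary document-term data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    grDevices,
    graphics,
    methods,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
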