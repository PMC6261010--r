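Package: meanbench
Title: Benchmark Estimators for Judging the Accuracy of Sample Means
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for deciding whether sample means in a balanced
    p-condition experiment are accurate enough to interpret.  Implements
    two deliberately uninformative benchmark estimators of condition
    means, the zero estimator (complete pooling to the grand mean) and a
    shrinkage-scaled random estimator, together with closed-form
    mean-squared-error comparisons, minimum-sample-size thresholds
    expressed through Cohen's f-squared, noncentral-F power analysis for
    the one-way ANOVA, a hierarchical-Bayes shrinkage estimator fit by
    Gibbs sampling, and a Monte-Carlo engine for verifying the closed
    forms under normal and non-normal error distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
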