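Package: paibrl
Title: Explainable Patient Selection with Personalized Advantage Index and
    Bayesian Rule Lists
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies treatment-indicated patient subgroups in two-arm
    randomized controlled trials with an explainable two-stage pipeline.
    Stage one fits an elastic-net outcome regression with treatment-arm
    interactions, predicts actual and counterfactual end-of-trial scores for
    every patient, and thresholds the resulting Personalized Advantage Index
    (PAI) into treatment-indicated and rest-indicated labels. Stage two
    learns a Bayesian Rule List (BRL) classifier over those labels by
    Metropolis-Hastings sampling of ordered conjunctive rules, yielding
    if-then-else statements with posterior class probabilities and bootstrap
    confidence intervals. Evaluation utilities provide stratified k-fold
    cross-validation, Cohen's d treatment effect sizes, a repeated-subgrouping
    significance test, and labeling-consistency summaries. A synthetic trial
    generator with a planted rule-defined responsive subgroup makes the whole
    pipeline testable without access to restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    pROC,
    stats,
    utils,
    withr,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
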