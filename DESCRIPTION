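Package: stratikit
Title: Risk-Stratified Patient Management Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating risk-stratified chronic-disease
    management programs from electronic-health-record style data. Provides a
    seeded synthetic cohort generator with known ground truth, cohort and
    outcome definitions for asthma, patient/physician-profile/environmental
    feature construction, predictive models of acute-care outcomes and costs
    with stratified cross-validation, minority-class rebalancing, backward
    elimination and feature merging, class association rule mining to explain
    high-risk predictions and attach tailored interventions, a greedy
    cost-delta optimizer for risk-strata thresholds under program capacities,
    a policy outcome simulator with sensitivity grids, and the design-stage
    power and sample-size calculations for the evaluation protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    pROC,
    rpart,
    ranger,
    glmnet,
    xgboost,
    class
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
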