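Package: dermpolicy
Title: Reward-Based Reinforcement Learning Decision Support for Skin
    Lesion Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision layer for multiclass skin-lesion classifiers that turns
    class probabilities, logits and feature vectors into management decisions
    under clinician preferences encoded as reward tables. Implements deep
    Q-learning over classifier state vectors (replay buffer, target network,
    epsilon-greedy exploration, Huber loss), a threshold-hierarchy policy, a
    naive top-1 policy, and the analytic expected-reward (Bayes) policy that
    serves as an oracle on calibrated data. Ships a synthetic classifier-output
    simulator with class-conditional Gaussian features and analytic posteriors,
    patient-cohort generators matching published dataset compositions,
    Shannon-entropy uncertainty analysis, ROC operating-point comparison and
    patient-level management summaries across three clinical scenarios:
    binary excise/dismiss, multiclass with local therapy, and patient-centered
    monitoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
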