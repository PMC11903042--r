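Package: metacontrol
Title: Simulation and Analysis of Meta-Cognition and Meta-Control in
    Model-Based/Model-Free Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying metacognition and meta-control in
    reinforcement learning and perceptual decision-making. Simulates a
    two-outcome bandit task (four people growing overlapping pairs of
    vegetables whose reward probabilities follow bounded Gaussian random
    walks) with a hybrid model-free/model-based agent that reports
    confidence, and a dot-density perceptual task with a one-up two-down
    staircase and a signal-detection observer with tunable metacognitive
    noise. Provides maximum-likelihood meta-d' estimation, hierarchical
    Bayesian M-ratio estimation across correlated within-subject
    conditions (via JAGS), one-trial-back model-free and model-based
    signature regressions with confidence interactions (via lme4),
    quadratic-scoring-rule confidence scoring, hybrid-model fitting by
    maximum likelihood, and simulate-then-regress recovery procedures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    lmerTest,
    rjags,
    coda,
    lhs,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
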