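Package: hybridrl
Title: Hybrid Neural-Cognitive Models of Human Reward Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, fitting and interpretation of a ladder of behavioural
    models for the restless four-armed bandit task: tabular Q-learning variants
    (a 48-model family including Simple RL and Best RL), hybrid neural-cognitive
    architectures (RL-ANN, Context-ANN, Memory-ANN) and a vanilla recurrent
    network, all trained by maximum likelihood (behavioural cloning) with
    participant-level train/validation/test splits. Includes a synthetic-cohort
    generator with heterogeneous agents and per-block Gaussian-random-walk
    reward schedules, a model-free behavioural battery (stay analyses, repeat
    streaks, cyclic responses, Lempel-Ziv-Welch compressibility, lagged choice
    regression) and interpretability tooling (teacher forcing, module probing,
    PCA of memory states, history decoding, priming and activity injection).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    glmnet
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
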