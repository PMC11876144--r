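Package: talsrx
Title: Multi-Model Fusion Scoring of KASP Genotyping Plate Quality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Assigns a 0-100 typing-effect score to KASP (kompetitive
    allele-specific PCR) genotyping plates from their two-channel (HEX/FAM)
    endpoint fluorescence values. Implements the TAL-SRX fusion scorer: a
    stacked-generalization layer (random-search-tuned random forest and
    particle-swarm-tuned RBF support vector machine feeding an XGBoost
    meta-learner through five-fold out-of-fold class probabilities) soft-voted
    with two neural branches (an ANN-LSTM hybrid and a Transformer encoder).
    Ships a generative simulator of plate morphologies for all eleven score
    classes of the 0-100 rubric, geometric cluster descriptors, three
    hyperparameter optimizers (random search, particle swarm, Bayesian
    optimization with a Gaussian-process surrogate), and a multi-class
    evaluation suite (macro precision/recall/F1, Cohen's kappa, one-vs-rest
    AUC, score-error vectors and score-band histograms).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    ranger,
    e1071,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
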