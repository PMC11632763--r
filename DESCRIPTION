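Package: bbbcliques
Title: Transparent Clique-Fragment Models of Blood-Brain Barrier Permeability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Featurizes small molecules as counts of "clique" fragments
    (smallest rings, bridged ring systems, and non-ring bonds), and uses
    these transparent descriptors to model blood-brain barrier permeability
    (BBBP). Provides a Gini random-forest classifier with
    mean-decrease-in-impurity importances, a discretized SMOTE oversampler
    for imbalanced training folds, a repeated k-fold evaluation harness
    reporting sensitivity, specificity, MCC and ROC AUC, and a Bernoulli
    naive-Bayes analysis that scores each fragment by its marginal
    probability of BBB permeation. Includes a reader for B3DB-style
    tab-separated molecule tables, exploratory statistics (molecular weight,
    Wildman-Crippen logP, log BB correlations), and a synthetic-data
    generator with planted fragment effects and exact analytic marginals for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ranger,
    jsonlite,
    optparse,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    e1071
SystemRequirements: OpenBabel (the 'obabel' command-line tool)
Config/testthat/edition: 3
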