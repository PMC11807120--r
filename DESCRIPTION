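Package: synthmcts
Title: Reaction-Aware Molecular Optimization by Conditional Sequence Models and Monte Carlo Tree Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates candidate molecules together with multi-step virtual
    synthetic routes. A reaction-template-conditioned encoder-decoder sequence
    model proposes single-step products from a reactant, a graph convolutional
    classifier ranks applicable reaction templates, and a Monte Carlo tree
    search with an upper-confidence-bound policy chains these virtual reactions
    into routes that maximize a QSAR (activity-probability) reward. Includes
    reaction-data preparation (reagent removal, Tanimoto pairing, SMILES
    tokenization, template-conditioned sequences), a desk-scale synthetic
    reaction grammar with a substructure-driven activity rule for end-to-end
    testing, and the full set of evaluation metrics (partial, perfect and top-n
    accuracy, uniqueness, internal diversity, reward-threshold fractions,
    scaffold retention, reaction-step distributions, starting-material filters,
    ligand efficiency).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
LinkingTo:
    Rcpp,
    RcppArmadillo
Imports:
    ChemmineOB,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    pROC,
    randomForest,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
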