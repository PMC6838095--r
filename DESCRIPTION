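Package: peakshift
Title: Adaptive-Peak Inference for Geometric Morphometric Data on Time-Calibrated Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying adaptive shape evolution from 3D landmark
    data and time-calibrated phylogenies containing fossil tips. Provides
    generalized Procrustes alignment with tangent-space projection,
    between-group principal component analysis with post-hoc projection of
    individuals and fossils, multivariate phylogenetic signal (a
    high-dimensional generalization of Blomberg's K) and phylogenetic
    multivariate regression of shape on size with permutation tests,
    maximum-likelihood fitting of Brownian motion and multi-regime
    Ornstein-Uhlenbeck (Hansen) models, stepwise AICc detection of
    adaptive-peak shifts with convergence collapse, fossil-tip grafting and
    matrix-representation-with-parsimony (MRP) supertrees, and simulators
    with known ground truth for every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    phangorn,
    phytools,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
Suggests:
    mvtnorm,
    yaml,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
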