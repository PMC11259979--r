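Package: mdsustain
Title: Subtype and Stage Inference for Multimodal Biomarker Data with
    Missing Values
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits mixtures of ordered biomarker-progression sequences
    (Subtype and Stage Inference, SuStaIn) to cross-sectional matrices of
    covariate-corrected Z-scores in which any entry may be missing.  Each
    subtype is a strict ordering of Z-score events along a piecewise-linear
    trajectory model; missing observations are marginalised out of the data
    likelihood with a uniform density over each biomarker's Z-score range,
    so that incomplete subjects still inform subtyping and staging.
    Includes greedy multi-start sequence optimisation, EM over subtype
    memberships, hierarchical cluster splitting, Metropolis-Hastings
    sampling of positional uncertainty, a synthetic-data generator,
    comparator missing-data strategies (subject deletion, column-mean and
    K-nearest-neighbour imputation), evaluation metrics (Kendall sequence
    similarity, subtyping accuracy, staging error), and a control-referenced
    covariate-correction preprocessing pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    methods,
    stats,
    tools,
    utils,
    Rcpp,
    jsonlite,
    optparse
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
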