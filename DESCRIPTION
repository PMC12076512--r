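Package: profis
Title: Target-Focused Compound Library Design by Probing Continuous
    Fingerprint Space with Recurrent Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Generative design of target-focused and analog compound
    libraries. A stochastic encoder embeds binary molecular fingerprints
    (ECFP4 or Klekota-Roth substructure keys) in a low-dimensional
    continuous latent space and a recurrent (GRU) decoder maps latent
    vectors back to sequential molecular notations (SMILES, DeepSMILES or
    SELFIES). The latent space is searched with a QSAR-guided Bayesian
    optimizer under mu +/- k*sigma bounds with sequential domain
    reduction, and libraries are post-filtered by drug-likeness criteria.
    Includes molecule standardization, Bemis-Murcko scaffold grouping and
    scaffold-held-out splitting, fingerprint computation and controlled
    bit-flip noising for analog generation, nested cross-validated latent
    activity classifiers, a cosine-similarity distance-to-model
    applicability domain, and deterministic synthetic fixture generators.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    dplyr,
    tibble,
    tidyr,
    rlang,
    generics,
    igraph,
    ggplot2,
    stats,
    utils,
    methods,
    e1071,
    ranger,
    xgboost,
    nnet,
    pROC,
    lhs
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
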