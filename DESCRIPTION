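Package: phenoSampler
Title: Uncertainty Sampling of Gene Signatures in Phenotype Prediction
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Resampling-based analysis of the uncertainty space of two-class
    phenotype prediction from gene expression. Ranks probes by Fisher's ratio,
    searches smallest-scale k-NN signatures over ranked prefixes, and samples
    the set of equivalent high-accuracy signatures with a 75/25 holdout
    sampler, a Fisher's-ratio prior sampler, and a Random-Forest sampler.
    Posterior gene sampling-frequency tables, correlation networks over the
    most discriminatory genes, local gene-set over-representation analysis,
    and a linear-regression equivalence-region demonstrator are included,
    together with a synthetic-cohort generator with planted differential
    probes for end-to-end validation with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    randomForest,
    fgsea,
    yaml
Suggests:
    testthat (>= 3.0.0),
    class,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
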