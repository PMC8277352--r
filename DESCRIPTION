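Package: fosmap
Title: Brain-Wide c-Fos Activity Mapping of Ingroup-Biased Helping Behavior
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An analysis pipeline for brain-wide immediate-early-gene
    (c-Fos) activity mapping of social behavior in rats. Provides task
    partial least squares (PLS) with permutation testing of latent
    variables and bootstrap estimation of region-salience reliability;
    inter-region co-activation network inference with scale-free and
    small-world threshold selection, hub identification and Louvain
    community detection; an ensemble eigen-region multinomial-logistic
    procedure for finding condition-specific brain regions; fiber
    photometry isosbestic motion correction, dF/F computation and
    event-triggered averaging; helping-behavior session statistics
    (Cochran's Q, Friedman, opener classification, zone analyses); and
    seeded synthetic-data generators emulating every input so the full
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    cluster,
    igraph,
    jsonlite,
    yaml
Suggests:
    nnet,
    testthat (>= 3.0.0),
    knitr
biocViews: GeneExpression, Network, GraphAndNetwork, Clustering
Config/testthat/edition: 3
RoxygenNote: 7.3.3
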