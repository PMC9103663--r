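Package: hubsig
Title: Frequency-Weighted Interactome Hub Signatures of Tumor Aggressiveness
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies molecular signatures that separate highly aggressive
    from less aggressive cancer types by combining per-sample upregulated-gene
    calls with protein-protein interaction connectivity. Implements the
    normalized-count times connection-number gene score over signaling-pathway
    genes, variance filtering with class-exclusive gene handling, an exclusive
    hub-boundary search, nonparametric cross-type comparisons, principal
    component analysis with per-gene variance contributions, hierarchical
    clustering of cancer types, random-forest classification of individual
    samples with out-of-bag error and Gini importance, and mapping of selected
    genes onto the interactome (major component, bridging paths, Cytoscape
    export). A seeded synthetic-data generator (scale-free interactome,
    overlapping pathway annotations, class-structured upregulation cohorts,
    negative-binomial paired counts) makes the whole pipeline testable end to
    end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    randomForest,
    jsonlite,
    yaml,
    withr,
    ape
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'interactome.R'
    'synthcohort.R'
    'upcall.R'
    'score.R'
    'groupstats.R'
    'hubsig-package.R'
    'pcaclass.R'
    'rfclass.R'
    'netx.R'
    'pipeline.R'
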