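Package: phnet
Title: Persistent Homology Analysis of Metabolic Brain Connectivity Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds neurotransmitter-pathway metabolic connectivity networks
    from subject-by-region FDG-PET uptake tables and analyses them with
    zero-dimensional persistent homology. Provides Pearson-correlation
    networks with the 1 - |r| distance transform, exact Betti-0 curves,
    barcodes, minimum spanning trees, single-linkage ultrametrics and
    dendrograms, the SIP (size of integrated persistence) area-under-curve
    statistic, weighted graph indices (characteristic path length, network
    diameter, eigenvector centrality), permutation tests between diagnostic
    groups, and a synthetic multi-group cohort generator with controllable
    within-pathway connectivity for validation without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    MASS,
    yaml,
    jsonlite,
    igraph,
    ape,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'atlas.R'
    'connectivity.R'
    'persistence.R'
    'graph-metrics.R'
    'group-stats.R'
    'synthetic.R'
    'pipeline.R'
    'phnet-package.R'
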