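Package: drugSimNet
Title: Network-Based Drug Repositioning from Drug Similarity Networks
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds cancer-related drug similarity networks by combining
    hypergeometric enrichment of drug targets in hallmark gene sets
    (functional similarity) with Jaccard similarity of ATC code prefixes
    (clinical therapeutic similarity), scores every drug against a seed set
    of known therapeutics by Random Walk with Restart under unweighted and
    integer-ratio edge-weighting patterns, screens candidates for stability
    under delete-n-out seed resampling, and filters by CRISPR gene-effect
    essentiality of drug targets to nominate repositionable drugs. Includes
    a synthetic scenario generator with planted structure for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    igraph,
    jsonlite,
    yaml,
    S4Vectors,
    IRanges,
    SummarizedExperiment
Suggests: testthat (>= 3.0.0), optparse, knitr
Config/testthat/edition: 3
biocViews: Network, GraphAndNetwork, GeneSetEnrichment, Pharmacogenomics
RoxygenNote: 7.3.3
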