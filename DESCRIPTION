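Package: TEnet
Title: Network Analysis of Transposable Element Evolution
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and analyses networks that describe transposable element
    (TE) evolution across genomes: monopartite sequence-similarity networks of
    individual TE copies weighted by alignment bitscore, bipartite genome-TE
    content networks under four abundance metrics, and a phylogeny-collapsed
    "orthonetwork" that adds genome-genome edges from shared orthogroup counts.
    Provides Louvain and connected-component clustering with rand-index
    concordance, mixed-cluster and cryptic-similarity enrichment analysis,
    degree and singleton statistics with Wilcoxon group comparisons, family
    knockout perturbation experiments, Pfam-domain based activity
    classification with a singleton bootstrap, and a synthetic landscape
    generator with planted clusters, convergent segments and horizontal
    transfer events so every stage can be validated against known ground
    truth. Parsers are included for RepeatMasker annotation tables, tabular
    alignment hits, HMMER domain tables and shared-orthogroup matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    xml2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
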