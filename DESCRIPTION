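Package: strucfun
Title: Structure-Based Protein Function Prediction with Graph
    Convolutional Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Multi-label protein function prediction from residue contact
    maps with a graph convolutional network over Kipf-Welling normalized
    adjacency, residue features from a two-layer LSTM protein language
    model fused with one-hot encodings, a DeepGO-style one-dimensional
    CNN sequence baseline, and gradient-weighted class activation mapping
    for residue-level localization of functional sites. Includes contact
    map construction under CA-CA, ANY-ANY and neighbor-atom definitions,
    Gene Ontology label-space construction (evidence filtering, DAG
    propagation, information content, term selection, class weights),
    CAFA-style evaluation (protein-centric Fmax, term-centric AUPR,
    bootstrap summaries), and a synthetic bead-chain structure generator
    with planted, spatially clustered functional motifs so that every
    stage is testable without external corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    igraph,
    withr,
    Biostrings,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'ontology.R'
    'features.R'
    'cnn.R'
    'contacts.R'
    'gcn.R'
    'metrics.R'
    'gradcam.R'
    'lstm.R'
    'synthetic.R'
    'pipeline.R'
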