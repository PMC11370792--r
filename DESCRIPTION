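Package: atrogex
Title: Imaging Transcriptomics of Cortical Atrophy in FTLD Subtypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Links regional cortical atrophy in frontotemporal lobar
    degeneration (FTLD) subtypes to regional gene expression. Provides
    W-score normative atrophy modelling, a simplified Allen Human Brain
    Atlas style expression-preparation pipeline, spatial map-gene
    correlation with variogram-matched surrogate permutation testing,
    gene-set overlap and over-representation statistics, GU(GT)-repeat
    scoring of gene sequences, regional co-expression graphs,
    connectivity-based disease-epicentre assignment, and synthetic-data
    generators that emulate the statistical structure of all inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
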