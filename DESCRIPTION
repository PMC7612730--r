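Package: tmestruct
Title: Discovery of Recurrent Multicellular Structures in the Tumor
    Microenvironment from Multiplexed Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A multitiered spatial analysis pipeline for highly multiplexed
    tissue imaging of solid tumors. Starting from segmented single-cell
    tables (centroid coordinates and per-marker ion counts), the package
    performs spillover compensation, arcsinh expression transformation,
    epithelial/TME compartment assignment, self-organizing-map plus
    graph-community phenotyping, tissue-interface enrichment modeling,
    random-walk community detection on cell-contact graphs, consensus
    clustering of community connectivity profiles into recurrent
    multicellular TME structures, out-of-sample structure classification,
    and downstream genomic-association and survival analyses. A
    seed-deterministic synthetic-cohort generator with planted phenotype
    and structure archetypes makes every stage testable without access to
    raw imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    class,
    igraph,
    mclust,
    randomForest,
    glmnet,
    pROC,
    survival,
    pracma,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
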