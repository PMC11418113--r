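Package: OvaCMS
Title: Consensus Molecular Subtyping of Ovarian Cancer from Bulk to Single-Cell
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrated pipeline for consensus molecular subtyping of
    ovarian tumors from merged multi-cohort expression data. Implements
    consensus non-negative matrix factorization clustering with cophenetic
    model selection and silhouette-based sample filtering, purity-based
    least-squares deconvolution of cancer and stromal compartment expression,
    directional relative-crosstalk scoring of ligand-receptor pairs between
    compartments and between single-cell populations, binned-control subtype
    scoring of malignant epithelial cells with hybrid-cell filtering,
    hypergeometric selection of subtype-specific coexpression modules, and a
    LASSO-Cox prognostic gene-signature risk model including the published
    ten-gene overall survival score. Ships a synthetic-data generator that
    emulates the multi-cohort, mixed-compartment, survival-annotated
    structure of the real data so the whole pipeline can be exercised and
    tested without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    glmnet,
    survival,
    jsonlite,
    yaml,
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust,
    cluster,
    fgsea,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Transcriptomics, GeneExpression, Clustering, Survival, SingleCell
RoxygenNote: 7.3.3
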