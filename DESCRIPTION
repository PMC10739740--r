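Package: comodmr
Title: Co-Expression Modules and Master Regulators for Case-Control
    Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Inference chain from a bulk RNA-seq count matrix to
    phenotype-associated co-expression modules and a genetically supported
    master-regulator call. Implements count QC and variable-gene selection,
    cell-type deconvolution covariates by non-negative least squares,
    signed-hybrid weighted co-expression networks with topological overlap,
    module eigengenes, module membership and gene significance, eigengene
    logistic-regression association with FDR control, hypergeometric
    over-representation analysis, Bayesian colocalisation of GWAS and eQTL
    summary statistics via Wakefield approximate Bayes factors, SNP-to-gene
    annotation with promoter-capture Hi-C support, and hub-protein
    identification in a protein-protein interaction network with a
    max-degree permutation test. A synthetic-data module generates every
    input with known ground truth so the whole pipeline is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    igraph,
    pracma,
    fgsea,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
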