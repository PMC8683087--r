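Package: pluteusAtlas
Title: Downstream Analysis of a Clustered Single-Cell Atlas of the Sea Urchin Pluteus Larva
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Reusable, tested implementations of the downstream analyses
    applied to a clustered single-cell RNA-seq atlas of the sea urchin
    early pluteus larva: per-cluster pseudobulk expression profiling and
    expressed-gene calling, rank-sum marker detection with detection-fraction
    filters, neighbor-joining cell-type trees with gene-resampling bootstrap
    supports, germ-layer transcription-factor set comparisons, an
    independent-swap matrix-randomization test for gene-panel co-expression
    in a target subcluster, and intersection of subcluster gene sets with a
    bulk knockdown differential-expression table. A negative-binomial
    synthetic-atlas generator with planted ground truth (cluster tree,
    markers, co-expressed panel, knockdown effects) makes every stage
    testable at desk scale without the deposited data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    ape,
    jsonlite,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: SingleCell, Transcriptomics, Phylogenetics, Software
RoxygenNote: 7.3.3
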