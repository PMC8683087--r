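# S4 containers for the downstream-analysis results.
#
# The count data themselves live in a SingleCellExperiment (assay "counts",
# colData columns "cluster" / "subcluster" / "replicate"); the classes below
# hold derived objects that have invariants worth enforcing.

#' Per-cluster expression profile
#'
#' Pseudobulk summary of a clustered count matrix: for every cluster the
#' counts-per-million (CPM) average expression of each gene and the fraction
#' of cells in which the gene is detected (count > 0).  Rows are clusters,
#' columns are genes.  Each CPM row sums to one million whenever the cluster
#' has any counts, so values are directly comparable to the "transcripts per
#' million" scale on which the expressed-gene rule (> 3) operates.
#'
#' @slot meanCPM numeric matrix (clusters x genes) of pseudobulk CPM.
#' @slot pctExpressing numeric matrix (clusters x genes) of detection
#'   fractions in `[0, 1]`.
#' @slot nCells named integer vector, cells per cluster.
#'
#' @seealso [clusterProfile()], [callExpressed()], [dotplotTable()]
#' @export
setClass("ClusterProfile",
    representation(
        meanCPM = "matrix",
        pctExpressing = "matrix",
        nCells = "integer"
    )
)

setValidity("ClusterProfile", function(object) {
    m <- object@meanCPM
    p <- object@pctExpressing
    msg <- character()
    if (!identical(dim(m), dim(p)))
        msg <- c(msg, "meanCPM and pctExpressing dimensions differ")
    if (is.null(rownames(m)) || is.null(colnames(m)))
        msg <- c(msg, "meanCPM must have cluster rownames and gene colnames")
    if (!identical(rownames(m), names(object@nCells)))
        msg <- c(msg, "nCells names must match profile clusters")
    if (any(m < 0)) msg <- c(msg, "meanCPM entries must be non-negative")
    if (any(p < -1e-12) || any(p > 1 + 1e-12))
        msg <- c(msg, "pctExpressing must lie in [0, 1]")
    rs <- rowSums(m)
    bad <- rs > 0 & abs(rs - 1e6) > 1e-6 * 1e6
    if (any(bad))
        msg <- c(msg, sprintf("CPM rows must sum to 1e6 (offender: %s)",
                              rownames(m)[which(bad)[1L]]))
    if (length(msg)) msg else TRUE
})

#' Expressed-gene sets per cluster
#'
#' For each cluster, the genes whose pseudobulk average expression strictly
#' exceeds a CPM threshold (default 3, the "greater than three transcripts
#' per million" rule).
#'
#' @slot sets named list of character vectors, one per cluster.
#' @slot threshold numeric(1), the strict CPM cutoff.
#'
#' @seealso [callExpressed()], [expressedAnywhere()]
#' @export
setClass("ExpressedGeneSets",
    representation(sets = "list", threshold = "numeric")
)

setValidity("ExpressedGeneSets", function(object) {
    msg <- character()
    if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
        msg <- c(msg, "sets must be uniquely named by cluster")
    if (!all(vapply(object@sets, is.character, logical(1))))
        msg <- c(msg, "each set must be a character vector")
    if (length(object@threshold) != 1L || is.na(object@threshold))
        msg <- c(msg, "threshold must be a single number")
    if (length(msg)) msg else TRUE
})

#' Cell-type tree with bootstrap supports
#'
#' An unrooted tree over cluster labels with non-negative branch lengths,
#' plus optional per-bipartition bootstrap supports (integer percentages).
#' Supports are keyed by a canonical bipartition string: the leaf-label side
#' of the split *not* containing the alphabetically first leaf, sorted and
#' joined with `"|"`.
#'
#' @slot phylo an [ape::phylo] object (branch lengths required; node labels,
#'   when present, carry supports).
#' @slot supports named numeric vector of supports in `[0, 100]`, possibly
#'   empty.
#'
#' @seealso [neighborJoining()], [bootstrapSupports()], [writeNewick()]
#' @export
setClass("CellTypeTree",
    representation(phylo = "ANY", supports = "numeric")
)

setValidity("CellTypeTree", function(object) {
    msg <- character()
    if (!inherits(object@phylo, "phylo"))
        msg <- c(msg, "phylo slot must be an ape 'phylo' object")
    else {
        if (length(object@phylo$tip.label) < 3L)
            msg <- c(msg, "tree must have at least 3 leaves")
        if (anyDuplicated(object@phylo$tip.label))
            msg <- c(msg, "duplicate leaf labels")
        if (is.null(object@phylo$edge.length))
            msg <- c(msg, "tree must carry branch lengths")
        else if (any(object@phylo$edge.length < -1e-12))
            msg <- c(msg, "negative branch length")
    }
    s <- object@supports
    if (length(s)) {
        if (is.null(names(s))) msg <- c(msg, "supports must be named")
        if (any(s < 0 | s > 100)) msg <- c(msg, "supports must lie in [0, 100]")
    }
    if (length(msg)) msg else TRUE
})

#' Ground truth of a synthetic atlas
#'
#' Everything the generator planted: the cluster tree, the expected CPM of
#' every gene in every cluster, marker assignments, the co-expressed gene
#' panel and its target subcluster, and (after [simulateKdDe()]) the signed
#' knockdown effects.
#'
#' @slot plantedTree a [CellTypeTree] (or NULL when fewer than 3 clusters).
#' @slot clusterMeans numeric matrix (clusters x genes) of expected CPM.
#' @slot markerOf named character vector mapping marker genes to clusters.
#' @slot panelGenes character vector, the planted panel.
#' @slot panelCluster character(1), the cluster (cell family) hosting the
#'   panel's target subcluster.
#' @slot panelTarget character(1), the target subcluster label.
#' @slot kdEffects named numeric vector of planted signed log fold changes
#'   (empty until a knockdown table is simulated).
#' @slot params list of generator settings.
#'
#' @seealso [simulateAtlas()], [simulateKdDe()]
#' @export
setClass("AtlasTruth",
    representation(
        plantedTree = "ANY",
        clusterMeans = "matrix",
        markerOf = "character",
        panelGenes = "character",
        panelCluster = "character",
        panelTarget = "character",
        kdEffects = "numeric",
        params = "list"
    )
)

setValidity("AtlasTruth", function(object) {
    msg <- character()
    if (!is.null(object@plantedTree) && !is(object@plantedTree, "CellTypeTree"))
        msg <- c(msg, "plantedTree must be a CellTypeTree or NULL")
    if (any(object@clusterMeans < 0))
        msg <- c(msg, "clusterMeans must be non-negative")
    if (length(object@markerOf) && length(object@panelGenes) &&
        any(names(object@markerOf) %in% object@panelGenes))
        msg <- c(msg, "marker genes and panel genes must be disjoint")
    if (length(object@panelGenes) &&
        !all(object@panelGenes %in% colnames(object@clusterMeans)))
        msg <- c(msg, "panel genes must belong to the gene catalogue")
    if (length(msg)) msg else TRUE
})

#' Result of the independent-swap co-expression test
#'
#' Observed versus randomized expressed-gene counts for a gene panel in a
#' target subcluster, the 2x2 contingency table built from them, the
#' chi-squared statistic with its p-value, and the auxiliary empirical
#' permutation p-value computed from the per-replicate counts.
#'
#' @slot panel character vector of panel gene IDs.
#' @slot target character(1), target subcluster label.
#' @slot G integer(1), panel size.
#' @slot kObs integer(1), panel genes expressed in the observed data.
#' @slot kRandMean numeric(1), mean expressed count over randomizations.
#' @slot kRandRounded integer(1), that mean rounded half away from zero.
#' @slot replicateCounts integer vector of per-replicate expressed counts.
#' @slot table 2x2 numeric matrix, rows {actual, randomized} x columns
#'   {expressed, not expressed}.
#' @slot chi2,p chi-squared statistic and p-value for the table.
#' @slot pEmpirical numeric(1), `(1 + #\{replicates >= kObs\}) / (R + 1)`.
#' @slot params list (n_swap_iters, n_replicates, rule, seed, ...).
#'
#' @seealso [coexpressionTest()]
#' @export
setClass("CoexpressionResult",
    representation(
        panel = "character",
        target = "character",
        G = "integer",
        kObs = "integer",
        kRandMean = "numeric",
        kRandRounded = "integer",
        replicateCounts = "integer",
        table = "matrix",
        chi2 = "numeric",
        p = "numeric",
        pEmpirical = "numeric",
        params = "list"
    )
)

setValidity("CoexpressionResult", function(object) {
    msg <- character()
    if (object@kObs > object@G) msg <- c(msg, "kObs cannot exceed panel size")
    if (!identical(dim(object@table), c(2L, 2L)))
        msg <- c(msg, "table must be 2x2")
    if (any(object@table < 0)) msg <- c(msg, "table entries must be >= 0")
    if (any(abs(rowSums(object@table) - object@G) > 1e-9))
        msg <- c(msg, "table rows must sum to the panel size")
    if (object@p < 0 || object@p > 1) msg <- c(msg, "p must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})
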