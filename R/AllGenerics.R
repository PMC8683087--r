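#' @name accessors
#' @title Accessors for pluteusAtlas S4 classes
#'
#' @description Small accessor generics so downstream code never touches
#' slots directly: `meanCPM()` and `pctExpressing()` return the cluster x
#' gene summary matrices of a [ClusterProfile-class]; `nCells()` the per
#' cluster cell counts; `geneSets()` / `cpmThreshold()` /
#' `expressedAnywhere()` query an [ExpressedGeneSets-class];
#' `asPhylo()` / `leafLabels()` / `supportValues()` / `bipartitionSets()` a
#' [CellTypeTree-class]; `truthTree()`, `truthMeans()`,
#' `markerAssignments()`, `panelGeneSet()` and `kdEffects()` an
#' [AtlasTruth-class]; `replicateCounts()` and `contingencyTable()` a
#' [CoexpressionResult-class].
#'
#' @param x an object of the documented class.
#' @return the slot contents described above.
#'
#' @examples
#' sim <- simulateAtlas(nClusters = 4, cellsPerCluster = 30, nGenes = 120,
#'                      seed = 1)
#' prof <- clusterProfile(sim$sce)
#' dim(meanCPM(prof))
#' nCells(prof)
NULL

#' @rdname accessors
#' @export
setGeneric("meanCPM", function(x) standardGeneric("meanCPM"))
#' @rdname accessors
#' @export
setGeneric("pctExpressing", function(x) standardGeneric("pctExpressing"))
#' @rdname accessors
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))
#' @rdname accessors
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))
#' @rdname accessors
#' @export
setGeneric("cpmThreshold", function(x) standardGeneric("cpmThreshold"))
#' @rdname accessors
#' @export
setGeneric("expressedAnywhere", function(x) standardGeneric("expressedAnywhere"))
#' @rdname accessors
#' @export
setGeneric("asPhylo", function(x) standardGeneric("asPhylo"))
#' @rdname accessors
#' @export
setGeneric("leafLabels", function(x) standardGeneric("leafLabels"))
#' @rdname accessors
#' @export
setGeneric("supportValues", function(x) standardGeneric("supportValues"))
#' @rdname accessors
#' @export
setGeneric("bipartitionSets", function(x) standardGeneric("bipartitionSets"))
#' @rdname accessors
#' @export
setGeneric("truthTree", function(x) standardGeneric("truthTree"))
#' @rdname accessors
#' @export
setGeneric("truthMeans", function(x) standardGeneric("truthMeans"))
#' @rdname accessors
#' @export
setGeneric("markerAssignments", function(x) standardGeneric("markerAssignments"))
#' @rdname accessors
#' @export
setGeneric("panelGeneSet", function(x) standardGeneric("panelGeneSet"))
#' @rdname accessors
#' @export
setGeneric("kdEffects", function(x) standardGeneric("kdEffects"))
#' @rdname accessors
#' @export
setGeneric("replicateCounts", function(x) standardGeneric("replicateCounts"))
#' @rdname accessors
#' @export
setGeneric("contingencyTable", function(x) standardGeneric("contingencyTable"))

## ---- ClusterProfile ----

#' @rdname accessors
#' @export
setMethod("meanCPM", "ClusterProfile", function(x) x@meanCPM)
#' @rdname accessors
#' @export
setMethod("pctExpressing", "ClusterProfile", function(x) x@pctExpressing)
#' @rdname accessors
#' @export
setMethod("nCells", "ClusterProfile", function(x) x@nCells)

setMethod("show", "ClusterProfile", function(object) {
    cat(sprintf("ClusterProfile: %d clusters x %d genes\n",
                nrow(object@meanCPM), ncol(object@meanCPM)))
    cat("clusters:", paste(head(rownames(object@meanCPM), 8), collapse = ", "),
        if (nrow(object@meanCPM) > 8) "..." else "", "\n")
    cat("cells per cluster:",
        paste(head(object@nCells, 8), collapse = ", "),
        if (length(object@nCells) > 8) "..." else "", "\n")
})

## ---- ExpressedGeneSets ----

#' @rdname accessors
#' @export
setMethod("geneSets", "ExpressedGeneSets", function(x) x@sets)
#' @rdname accessors
#' @export
setMethod("cpmThreshold", "ExpressedGeneSets", function(x) x@threshold)
#' @rdname accessors
#' @export
setMethod("expressedAnywhere", "ExpressedGeneSets", function(x)
    sort(unique(unlist(x@sets, use.names = FALSE))))

setMethod("show", "ExpressedGeneSets", function(object) {
    cat(sprintf("ExpressedGeneSets: %d clusters, CPM threshold > %g\n",
                length(object@sets), object@threshold))
    cat(sprintf("expressed anywhere: %d genes\n",
                length(expressedAnywhere(object))))
})

## ---- CellTypeTree ----

#' @rdname accessors
#' @export
setMethod("asPhylo", "CellTypeTree", function(x) x@phylo)
#' @rdname accessors
#' @export
setMethod("leafLabels", "CellTypeTree", function(x) x@phylo$tip.label)
#' @rdname accessors
#' @export
setMethod("supportValues", "CellTypeTree", function(x) x@supports)
#' @rdname accessors
#' @export
setMethod("bipartitionSets", "CellTypeTree", function(x)
    .bipartitionKeys(x@phylo))

setMethod("show", "CellTypeTree", function(object) {
    cat(sprintf("CellTypeTree: %d leaves, %d internal bipartitions\n",
                length(object@phylo$tip.label),
                length(.bipartitionKeys(object@phylo))))
    if (length(object@supports))
        cat(sprintf("bootstrap supports: min %g, median %g, max %g\n",
                    min(object@supports), stats::median(object@supports),
                    max(object@supports)))
})

## ---- AtlasTruth ----

#' @rdname accessors
#' @export
setMethod("truthTree", "AtlasTruth", function(x) x@plantedTree)
#' @rdname accessors
#' @export
setMethod("truthMeans", "AtlasTruth", function(x) x@clusterMeans)
#' @rdname accessors
#' @export
setMethod("markerAssignments", "AtlasTruth", function(x) x@markerOf)
#' @rdname accessors
#' @export
setMethod("panelGeneSet", "AtlasTruth", function(x) x@panelGenes)
#' @rdname accessors
#' @export
setMethod("kdEffects", "AtlasTruth", function(x) x@kdEffects)

setMethod("show", "AtlasTruth", function(object) {
    cat(sprintf("AtlasTruth: %d clusters x %d genes\n",
                nrow(object@clusterMeans), ncol(object@clusterMeans)))
    cat(sprintf("planted markers: %d; panel: %d genes in %s / %s\n",
                length(object@markerOf), length(object@panelGenes),
                object@panelCluster, object@panelTarget))
    if (length(object@kdEffects))
        cat(sprintf("knockdown effects planted for %d genes\n",
                    length(object@kdEffects)))
})

## ---- CoexpressionResult ----

#' @rdname accessors
#' @export
setMethod("replicateCounts", "CoexpressionResult", function(x)
    x@replicateCounts)
#' @rdname accessors
#' @export
setMethod("contingencyTable", "CoexpressionResult", function(x) x@table)

setMethod("show", "CoexpressionResult", function(object) {
    cat(sprintf("Independent-swap co-expression test (target %s)\n",
                object@target))
    cat(sprintf("panel: %d genes; expressed observed: %d; randomized mean: %.2f (rounded %d)\n",
                object@G, object@kObs, object@kRandMean, object@kRandRounded))
    cat(sprintf("chi-squared = %.4g, p = %.4g; empirical p = %.4g (%d replicates, %d swap attempts)\n",
                object@chi2, object@p, object@pEmpirical,
                length(object@replicateCounts),
                object@params$n_swap_iters %||% NA))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
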