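# Synthetic-atlas generator.  Emulates the statistical structure the
# downstream analyses assume: clusters from three germ layers related by a
# planted tree (Brownian walk on log-means along its edges), cluster-specific
# marker genes, negative-binomial counts with lognormal library-size
# variation, one cell family carrying a rare gene panel co-expressed in a
# target subcluster, and a matched bulk knockdown DE table.

.padLabels <- function(prefix, n) {
    sprintf(paste0(prefix, "%0", nchar(n), "d"), seq_len(n))
}

#' Simulate a clustered single-cell atlas with known ground truth
#'
#' Cluster expected expression is generated by exponentiating a Brownian
#' walk (`sd = branchSd` per unit branch length) along the edges of a
#' planted binary tree over clusters, starting from a shared baseline;
#' markers multiply their own cluster by `2^markerLog2FC` (and all other
#' clusters by `markerBackground`); panel genes are a rare-transcript class
#' scaled by `panelBackground` everywhere and additionally by `panelEffect`
#' in the cells of the target subcluster of `panelCluster`.  Counts are
#' negative binomial with size `nbDispersion` (`Inf` switches to Poisson)
#' around the cell-level mean, which includes a lognormal library-size
#' factor (`librarySdLog`).  Everything planted is recorded in an
#' [AtlasTruth-class].
#'
#' @param nClusters number of clusters (>= 2 for tree simulation).
#' @param cellsPerCluster scalar or per-cluster vector of cell numbers.
#' @param nGenes number of genes.
#' @param germLayers optional named map cluster -> germ layer
#'   (`"ectoderm"`, `"mesoderm"`, `"endoderm"`); by default clusters are
#'   split into three contiguous thirds.
#' @param plantedTree optional [CellTypeTree-class] or [ape::phylo] over
#'   the cluster labels; by default a random binary topology with branch
#'   lengths uniform in `[0.5, 1]`.
#' @param branchSd Brownian step (log-mean units) per unit branch length.
#' @param markersPerCluster,markerLog2FC,markerBackground marker model.
#' @param nbDispersion negative-binomial size parameter (`Inf` = Poisson).
#' @param baselineMean expected baseline count per gene per cell.
#' @param librarySdLog sdlog of the mean-one lognormal library factor.
#' @param panelSize,panelCluster,panelEffect,panelBackground,panelTargetFrac
#'   panel model; `panelCluster` defaults to the last cluster, the target
#'   subcluster receives `panelTargetFrac` of the family's cells, and
#'   `panelEffect = 1` turns the planted co-expression off (the null).
#' @param nSubclusters subclusters of the panel family.
#' @param seed RNG seed; equal seeds give bit-identical output.
#' @return list with `sce` (annotated SingleCellExperiment, truth also in
#'   its metadata), `annotation` (data.frame cell_id / cluster / subcluster)
#'   and `truth` (an [AtlasTruth-class]).
#' @examples
#' sim <- simulateAtlas(nClusters = 4, cellsPerCluster = 30, nGenes = 200,
#'                      seed = 1)
#' sim$truth
#' @seealso [simulateKdDe()], [clusterProfile()], [coexpressionTest()]
#' @export
simulateAtlas <- function(nClusters = 20, cellsPerCluster = 100,
                          nGenes = 1000, germLayers = NULL,
                          plantedTree = NULL, branchSd = 0.4,
                          markersPerCluster = 10, markerLog2FC = 2,
                          markerBackground = 1, nbDispersion = 2,
                          baselineMean = 0.5, librarySdLog = 0.3,
                          panelSize = 20, panelCluster = NULL,
                          panelEffect = 25, panelBackground = 0.02,
                          panelTargetFrac = 0.1, nSubclusters = 4,
                          seed = NULL) {
    if (nClusters < 1) stop("config error: nClusters must be >= 1")
    if (nGenes < 1) stop("config error: nGenes must be >= 1")
    if (baselineMean <= 0 || (!is.infinite(nbDispersion) && nbDispersion <= 0))
        stop("config error: means and dispersions must be positive")
    if (markersPerCluster * nClusters + panelSize > nGenes)
        stop("config error: markersPerCluster * nClusters + panelSize ",
             "exceeds nGenes")
    if (!is.null(seed)) set.seed(seed)
    clusters <- .padLabels("C", nClusters)
    genes <- .padLabels("g", nGenes)
    ncells <- rep(cellsPerCluster, length.out = nClusters)
    if (any(ncells < 1)) stop("config error: empty cluster requested")
    panelCluster <- panelCluster %||% clusters[nClusters]
    if (!panelCluster %in% clusters)
        stop("config error: panelCluster not among cluster labels")
    if (is.null(germLayers)) {
        third <- ceiling(nClusters / 3)
        germLayers <- setNames(rep(c("ectoderm", "mesoderm", "endoderm"),
                                   each = third)[seq_len(nClusters)],
                               clusters)
    }

    ## planted tree and Brownian log-mean offsets
    phy <- NULL
    delta <- matrix(0, nClusters, nGenes, dimnames = list(clusters, genes))
    if (nClusters >= 3) {
        if (is.null(plantedTree)) {
            phy <- ape::rtree(nClusters, rooted = TRUE, tip.label = clusters)
            phy$edge.length <- runif(nrow(phy$edge), 0.5, 1)
        } else {
            phy <- if (is(plantedTree, "CellTypeTree")) asPhylo(plantedTree)
                   else plantedTree
            if (!setequal(phy$tip.label, clusters))
                stop("config error: plantedTree leaves must match clusters")
        }
        edge <- ape::reorder.phylo(phy, "cladewise")$edge
        len <- ape::reorder.phylo(phy, "cladewise")$edge.length
        nt <- length(phy$tip.label)
        val <- matrix(0, nt + phy$Nnode, nGenes)
        for (e in seq_len(nrow(edge))) {
            par <- edge[e, 1L]; ch <- edge[e, 2L]
            val[ch, ] <- val[par, ] +
                rnorm(nGenes, 0, branchSd * sqrt(len[e]))
        }
        delta[phy$tip.label, ] <- val[seq_len(nt), ]
    } else if (nClusters == 2) {
        delta[2, ] <- rnorm(nGenes, 0, branchSd)
    }

    ## cluster-level expected counts per cell
    mu <- baselineMean * exp(delta)

    ## markers: disjoint random gene assignment
    markerOf <- character(0)
    remaining <- genes
    if (markersPerCluster > 0) {
        mg <- sample(remaining, markersPerCluster * nClusters)
        markerOf <- setNames(rep(clusters, each = markersPerCluster), mg)
        for (g in names(markerOf)) {
            own <- markerOf[[g]]
            ownMean <- mu[own, g] * 2^markerLog2FC
            mu[, g] <- mu[, g] * markerBackground
            mu[own, g] <- ownMean
        }
        remaining <- setdiff(remaining, mg)
    }

    ## panel genes: rare everywhere, boosted in the target subcluster
    panelGenes <- character(0)
    if (panelSize > 0) {
        panelGenes <- sort(sample(remaining, panelSize))
        mu[, panelGenes] <- mu[, panelGenes] * panelBackground
    }

    ## subcluster layout within the panel family
    famIdx <- which(clusters == panelCluster)
    famCells <- ncells[famIdx]
    if (nSubclusters < 1) nSubclusters <- 1L
    nTarget <- if (nSubclusters == 1L) as.integer(famCells)
               else max(1L, as.integer(ceiling(panelTargetFrac * famCells)))
    targetLabel <- paste0(panelCluster, "_s1")

    ## draw counts cluster by cluster
    cellCluster <- rep(clusters, times = ncells)
    nCellsTot <- length(cellCluster)
    cellIds <- .padLabels("cell", nCellsTot)
    counts <- matrix(0L, nGenes, nCellsTot, dimnames = list(genes, cellIds))
    subclusterLab <- cellCluster
    offset <- 0L
    for (ci in seq_len(nClusters)) {
        ncc <- ncells[ci]
        cols <- offset + seq_len(ncc)
        lib <- rlnorm(ncc, meanlog = -librarySdLog^2 / 2,
                      sdlog = librarySdLog)
        M <- outer(mu[ci, ], lib)          # genes x cells of this cluster
        if (ci == famIdx) {
            rest <- ncc - nTarget
            subs <- if (nSubclusters == 1L) rep(targetLabel, ncc)
                else c(rep(targetLabel, nTarget),
                       if (rest > 0)
                           paste0(panelCluster, "_s",
                                  2L + (seq_len(rest) - 1L) %%
                                      (nSubclusters - 1L)))
            subclusterLab[cols] <- subs
            if (length(panelGenes) && panelEffect != 1)
                M[panelGenes, seq_len(nTarget)] <-
                    M[panelGenes, seq_len(nTarget)] * panelEffect
        }
        draw <- if (is.infinite(nbDispersion)) rpois(length(M), lambda = M)
                else rnbinom(length(M), mu = M, size = nbDispersion)
        counts[, cols] <- matrix(as.integer(draw), nrow = nGenes)
        offset <- offset + ncc
    }

    ## ground-truth expected CPM per cluster (library factors average to 1)
    muCluster <- mu
    if (length(panelGenes)) {
        fT <- nTarget / famCells
        muCluster[famIdx, panelGenes] <-
            mu[famIdx, panelGenes] * (fT * panelEffect + (1 - fT))
    }
    cpmTruth <- muCluster / rowSums(muCluster) * 1e6

    planted <- if (!is.null(phy)) {
        up <- ape::unroot(phy)
        .asCellTypeTree(up, supports = numeric(0))
    } else NULL

    truth <- new("AtlasTruth",
        plantedTree = planted,
        clusterMeans = cpmTruth,
        markerOf = markerOf,
        panelGenes = panelGenes,
        panelCluster = panelCluster,
        panelTarget = targetLabel,
        kdEffects = numeric(0),
        params = list(nClusters = nClusters, cellsPerCluster = ncells,
                      nGenes = nGenes, branchSd = branchSd,
                      markersPerCluster = markersPerCluster,
                      markerLog2FC = markerLog2FC,
                      markerBackground = markerBackground,
                      nbDispersion = nbDispersion,
                      baselineMean = baselineMean,
                      librarySdLog = librarySdLog,
                      panelSize = panelSize, panelEffect = panelEffect,
                      panelBackground = panelBackground,
                      panelTargetFrac = panelTargetFrac,
                      nSubclusters = nSubclusters,
                      germLayers = germLayers, seed = seed))

    ann <- data.frame(cell_id = cellIds, cluster = cellCluster,
                      subcluster = subclusterLab,
                      stringsAsFactors = FALSE)
    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = as(counts, "CsparseMatrix")),
        colData = S4Vectors::DataFrame(cluster = cellCluster,
                                       subcluster = subclusterLab,
                                       row.names = cellIds))
    S4Vectors::metadata(sce)$truth <- truth
    list(sce = sce, annotation = ann, truth = truth)
}

#' Simulate a matched bulk knockdown DE table
#'
#' Selects `nTargets` genes from the panel family's expressed set (truth
#' CPM > `thresholdCPM` in that cluster), plants a negative log fold change
#' on `round(fracDown * nTargets)` of them (rounded half away from zero)
#' and a positive one on the rest, with adjusted p-values below `alpha`;
#' every other catalogue gene is included as non-significant background.
#' The planted signed effects are recorded in the returned truth.
#'
#' @param truth an [AtlasTruth-class] from [simulateAtlas()].
#' @param fracDown fraction of targets downregulated (the knockdown study
#'   reported 65\%).
#' @param nTargets number of significant target genes (the study
#'   intersected 249).
#' @param alpha significance level separating targets from background.
#' @param lfcMean,lfcSd magnitude distribution of planted log fold changes.
#' @param thresholdCPM expressed-gene cutoff applied to the truth CPM.
#' @param seed RNG seed.
#' @return list with `de` (data.frame gene_id / log_fc / adj_p /
#'   significant) and `truth` (updated with `kdEffects`).
#' @examples
#' sim <- simulateAtlas(nClusters = 3, cellsPerCluster = 20, nGenes = 400,
#'                      seed = 2)
#' kd <- simulateKdDe(sim$truth, fracDown = 0.65, nTargets = 100, seed = 2)
#' table(sign(kd$de$log_fc[kd$de$significant]))
#' @export
simulateKdDe <- function(truth, fracDown = 0.65, nTargets = 249,
                         alpha = 0.05, lfcMean = 1.5, lfcSd = 0.5,
                         thresholdCPM = 3, seed = NULL) {
    stopifnot(is(truth, "AtlasTruth"))
    if (fracDown < 0 || fracDown > 1)
        stop("config error: fracDown must lie in [0, 1]")
    if (!is.null(seed)) set.seed(seed)
    cpm <- truthMeans(truth)[truth@panelCluster, ]
    expressed <- names(cpm)[cpm > thresholdCPM]
    if (nTargets > length(expressed))
        stop("config error: nTargets exceeds the ", length(expressed),
             " genes expressed in ", truth@panelCluster)
    targets <- sample(expressed, nTargets)
    nDown <- as.integer(.roundHalfAway(fracDown * nTargets))
    lfc <- abs(rnorm(nTargets, lfcMean, lfcSd))
    lfc[seq_len(nDown)] <- -lfc[seq_len(nDown)]
    adjT <- pmin(runif(nTargets, 0, alpha), alpha * (1 - 1e-9))
    others <- setdiff(colnames(truthMeans(truth)), targets)
    de <- data.frame(
        gene_id = c(targets, others),
        log_fc = c(lfc, rnorm(length(others), 0, 0.3)),
        adj_p = c(adjT, runif(length(others), alpha, 1)),
        stringsAsFactors = FALSE)
    de$significant <- de$adj_p < alpha
    de <- de[order(de$gene_id), , drop = FALSE]
    rownames(de) <- NULL
    truth@kdEffects <- setNames(lfc, targets)
    validObject(truth)
    list(de = de, truth = truth)
}
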