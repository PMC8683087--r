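# Quality filtering, pseudobulk cluster profiles, expressed-gene calling,
# marker detection, and the dotplot summary table.

#' Quality-control filter for a count matrix
#'
#' Two fixed passes, genes first, then cells: genes detected (count > 0) in
#' fewer than `minCells` cells are removed, then cells with fewer than
#' `minGenes` detected genes (counted on the retained genes) are removed.
#' The defaults implement the usual rule: genes transcribed in less than
#' three cells, and cells with less than a minimum of 200 transcribed
#' genes, are excluded.  A cell with exactly `minGenes` detected genes is
#' retained.  Applying the filter twice changes nothing.
#'
#' @param x a SingleCellExperiment (or matrix-like) of counts.
#' @param minCells minimum number of cells a gene must be detected in.
#' @param minGenes minimum number of detected genes a cell must have.
#' @return the filtered object, same class as the input.
#' @examples
#' sim <- simulateAtlas(nClusters = 3, cellsPerCluster = 20, nGenes = 100,
#'                      seed = 1)
#' dim(filterQC(sim$sce, minCells = 3, minGenes = 20))
#' @export
filterQC <- function(x, minCells = 3, minGenes = 200) {
    m <- .countsOf(x)
    geneKeep <- Matrix::rowSums(m > 0) >= minCells
    m2 <- m[geneKeep, , drop = FALSE]
    cellKeep <- Matrix::colSums(m2 > 0) >= minGenes
    if (!any(cellKeep))
        warning("QC filter removed every cell")
    if (is(x, "SummarizedExperiment"))
        x[geneKeep, cellKeep]
    else
        m2[, cellKeep, drop = FALSE]
}

.clusterLabels <- function(x, level = c("cluster", "subcluster")) {
    level <- match.arg(level)
    cd <- SummarizedExperiment::colData(x)
    if (!level %in% colnames(cd))
        stop("no '", level, "' column in colData; annotate the cells first")
    lab <- as.character(cd[[level]])
    bad <- is.na(lab) | lab == ""
    if (any(bad))
        stop("cells missing ", level, " annotation: ",
             paste(head(colnames(x)[bad], 5), collapse = ", "),
             if (sum(bad) > 5) sprintf(" (+%d more)", sum(bad) - 5) else "")
    lab
}

#' Per-cluster pseudobulk expression profile
#'
#' For each cluster (or subcluster): `meanCPM[c, g] = 1e6 * sum of counts of
#' g over cells in c / sum of all counts in c` (pseudobulk counts per
#' million), and `pctExpressing[c, g]` = fraction of cells in c with
#' count > 0.  `method = "mean_cell"` instead averages per-cell CPM (each
#' cell scaled to one million first); rows still sum to 1e6 up to the cell
#' weighting.
#'
#' @param x an annotated SingleCellExperiment.
#' @param level `"cluster"` or `"subcluster"` colData column.
#' @param method `"pseudobulk"` (default) or `"mean_cell"`.
#' @return a [ClusterProfile-class]; clusters are sorted by label.
#' @examples
#' sim <- simulateAtlas(nClusters = 4, cellsPerCluster = 25, nGenes = 150,
#'                      seed = 3)
#' prof <- clusterProfile(sim$sce)
#' rowSums(meanCPM(prof))[1:2]    # 1e6 each
#' @seealso [callExpressed()], [dotplotTable()]
#' @export
clusterProfile <- function(x, level = c("cluster", "subcluster"),
                           method = c("pseudobulk", "mean_cell")) {
    level <- match.arg(level)
    method <- match.arg(method)
    m <- .countsOf(x)
    lab <- .clusterLabels(x, level)
    clusters <- sort(unique(lab))
    nc <- vapply(clusters, function(cl) sum(lab == cl), integer(1))
    if (any(nc == 0L)) {
        warning("dropping empty cluster(s): ",
                paste(clusters[nc == 0L], collapse = ", "))
        clusters <- clusters[nc > 0L]
        nc <- nc[nc > 0L]
    }
    genes <- rownames(m)
    cpm <- matrix(0, length(clusters), length(genes),
                  dimnames = list(clusters, genes))
    pct <- cpm
    for (cl in clusters) {
        sub <- m[, lab == cl, drop = FALSE]
        if (method == "pseudobulk") {
            pb <- Matrix::rowSums(sub)
            tot <- sum(pb)
            cpm[cl, ] <- if (tot > 0) 1e6 * pb / tot else 0
        } else {
            cellTot <- Matrix::colSums(sub)
            cellTot[cellTot == 0] <- 1
            cellCPM <- base::t(base::t(as.matrix(sub)) / cellTot) * 1e6
            cpm[cl, ] <- rowMeans(cellCPM)
        }
        pct[cl, ] <- Matrix::rowSums(sub > 0) / ncol(sub)
    }
    new("ClusterProfile", meanCPM = cpm, pctExpressing = pct,
        nCells = setNames(nc, clusters))
}

#' Call expressed genes per cluster
#'
#' A gene is "expressed" in a cluster when its average expression strictly
#' exceeds `threshold` CPM there (default 3: the greater-than-three
#' transcripts-per-million rule; a gene at exactly 3.0 is excluded).  The
#' anywhere-union (expressed in at least one cluster) is available through
#' [expressedAnywhere()] and defines the gene universe for tree building.
#'
#' @param profile a [ClusterProfile-class].
#' @param threshold strict CPM cutoff.
#' @return an [ExpressedGeneSets-class].
#' @export
callExpressed <- function(profile, threshold = 3) {
    stopifnot(is(profile, "ClusterProfile"))
    M <- meanCPM(profile)
    sets <- lapply(rownames(M), function(cl)
        colnames(M)[M[cl, ] > threshold])
    new("ExpressedGeneSets", sets = setNames(sets, rownames(M)),
        threshold = threshold)
}

## ---- rank-sum test ----

# Two-sided Wilcoxon rank-sum p-value for x vs y.
# Exact permutation enumeration when both groups have <= `exactMax`
# observations (ties handled exactly through average ranks); otherwise the
# normal approximation with tie-corrected variance and continuity
# correction.
.rankSumP <- function(x, y, exactMax = 10L) {
    nx <- length(x); ny <- length(y)
    N <- nx + ny
    r <- rank(c(x, y))
    W <- sum(r[seq_len(nx)])
    mu <- nx * (N + 1) / 2
    if (nx <= exactMax && ny <= exactMax) {
        combs <- utils::combn(N, nx)
        Ws <- colSums(matrix(r[combs], nrow = nx))
        mean(abs(Ws - mu) >= abs(W - mu) - 1e-9)
    } else {
        ties <- table(r)
        sig2 <- nx * ny / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
        if (sig2 <= 0) return(1)
        z <- (abs(W - mu) - 0.5) / sqrt(sig2)
        min(1, 2 * stats::pnorm(-max(0, z)))
    }
}

#' Cluster marker detection
#'
#' Markers of one cluster against all remaining cells.  A gene is tested
#' when it is detected (count > 0) in at least `minPct` of the cells of the
#' cluster or of the rest group (`filter = "or"`, the default reading of the
#' 0.01 min.pct detection filter; `"and"` requires both).  The test is a
#' two-sided Wilcoxon rank-sum on per-cell log-normalized expression
#' (counts scaled to 10,000 per cell, then `log1p`), exact by enumeration
#' when both groups have at most 10 cells and normal-approximated with tie
#' correction and continuity correction otherwise.  `log2_fc` compares the
#' pseudobulk CPM of the two groups with a pseudocount of 1; p-values are
#' Bonferroni-adjusted over the tested genes.
#'
#' @param x an annotated SingleCellExperiment.
#' @param cluster the cluster whose markers are sought.
#' @param minPct minimum detection fraction (default 0.01).
#' @param filter `"or"` or `"and"` combination of the two detection
#'   fractions.
#' @param level annotation level to use.
#' @return a data.frame (gene_id, cluster, log2_fc, pct_in, pct_out, p,
#'   p_adj) sorted by p_adj, then decreasing `|log2_fc|`.
#' @examples
#' sim <- simulateAtlas(nClusters = 3, cellsPerCluster = 30, nGenes = 150,
#'                      markersPerCluster = 5, markerLog2FC = 3, seed = 4)
#' mk <- findMarkers(sim$sce, cluster = "C1")
#' head(mk, 3)
#' @export
findMarkers <- function(x, cluster, minPct = 0.01,
                        filter = c("or", "and"),
                        level = c("cluster", "subcluster")) {
    filter <- match.arg(filter)
    level <- match.arg(level)
    m <- .countsOf(x)
    lab <- .clusterLabels(x, level)
    if (!cluster %in% lab) stop("unknown cluster: ", cluster)
    if (length(unique(lab)) < 2L) stop("need at least 2 clusters")
    inGrp <- lab == cluster
    if (sum(inGrp) < 3L)
        stop("cluster '", cluster, "' has fewer than 3 cells; ",
             "the rank-sum test is not attempted at that size")
    mIn <- m[, inGrp, drop = FALSE]
    mOut <- m[, !inGrp, drop = FALSE]
    pctIn <- Matrix::rowSums(mIn > 0) / ncol(mIn)
    pctOut <- Matrix::rowSums(mOut > 0) / ncol(mOut)
    tested <- if (filter == "or") pctIn >= minPct | pctOut >= minPct
              else pctIn >= minPct & pctOut >= minPct
    genes <- rownames(m)[tested]
    if (!length(genes))
        return(data.frame(gene_id = character(), cluster = character(),
                          log2_fc = numeric(), pct_in = numeric(),
                          pct_out = numeric(), p = numeric(),
                          p_adj = numeric()))
    # per-cell log normalization: counts / cell total * 1e4, log1p
    tot <- Matrix::colSums(m)
    tot[tot == 0] <- 1
    norm <- base::t(base::t(as.matrix(m[genes, , drop = FALSE])) / tot) * 1e4
    norm <- log1p(norm)
    pbIn <- Matrix::rowSums(mIn); pbOut <- Matrix::rowSums(mOut)
    cpmIn <- 1e6 * pbIn / max(1, sum(pbIn))
    cpmOut <- 1e6 * pbOut / max(1, sum(pbOut))
    p <- vapply(genes, function(g)
        .rankSumP(norm[g, inGrp], norm[g, !inGrp]), numeric(1))
    res <- data.frame(
        gene_id = genes,
        cluster = cluster,
        log2_fc = log2((cpmIn[genes] + 1) / (cpmOut[genes] + 1)),
        pct_in = pctIn[genes],
        pct_out = pctOut[genes],
        p = p,
        p_adj = pmin(1, p * length(genes)),
        row.names = NULL)
    res[order(res$p_adj, -abs(res$log2_fc), res$gene_id), , drop = FALSE]
}

#' Dotplot summary table
#'
#' The two quantities behind an expression dotplot, per (gene, cluster):
#' the detection fraction and the z-scored mean of `log1p(meanCPM)`, scaled
#' across clusters with the usual n-1 standard deviation (as `scale()`
#' does, so two clusters give z-scores of +/- 0.7071).  Genes with no
#' variance across clusters get z = 0.  Panel genes absent from the profile
#' are reported with a warning and skipped.
#'
#' @param profile a [ClusterProfile-class].
#' @param genes character vector of gene IDs (a panel).
#' @return a data.frame (gene_id, cluster, pct_expressing, avg_log_cpm,
#'   scaled_expression).
#' @export
dotplotTable <- function(profile, genes) {
    stopifnot(is(profile, "ClusterProfile"))
    M <- meanCPM(profile)
    genes <- as.character(genes)
    missing <- setdiff(genes, colnames(M))
    if (length(missing))
        warning("genes absent from profile: ",
                paste(missing, collapse = ", "))
    genes <- intersect(genes, colnames(M))
    if (!length(genes))
        return(data.frame(gene_id = character(), cluster = character(),
                          pct_expressing = numeric(),
                          avg_log_cpm = numeric(),
                          scaled_expression = numeric()))
    clusters <- rownames(M)
    L <- log1p(M[, genes, drop = FALSE])
    Z <- apply(L, 2L, function(v) {
        s <- stats::sd(v)
        if (is.na(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
    })
    Z <- matrix(Z, nrow = length(clusters),
                dimnames = list(clusters, genes))
    data.frame(
        gene_id = rep(genes, each = length(clusters)),
        cluster = rep(clusters, times = length(genes)),
        pct_expressing = as.vector(pctExpressing(profile)[, genes]),
        avg_log_cpm = as.vector(L),
        scaled_expression = as.vector(Z),
        row.names = NULL)
}
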