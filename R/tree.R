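# Cell-type tree reconstruction: expression distances over the expressed
# gene universe, neighbor joining, and gene-resampling bootstrap supports.

## ---- bipartition bookkeeping ----

# Tip sets below every node, in the tree's own node numbering.
.nodeTipSets <- function(phy) {
    nt <- length(phy$tip.label)
    nn <- phy$Nnode
    sets <- vector("list", nt + nn)
    for (i in seq_len(nt)) sets[[i]] <- phy$tip.label[i]
    edge <- ape::reorder.phylo(phy, "postorder")$edge
    for (e in seq_len(nrow(edge)))
        sets[[edge[e, 1L]]] <- c(sets[[edge[e, 1L]]], sets[[edge[e, 2L]]])
    sets
}

# Canonical key of the split {tips | rest}: the side not containing the
# alphabetically first leaf, sorted, joined with "|".  NA for trivial splits.
.splitKey <- function(tips, allTips) {
    ref <- min(allTips)
    side <- if (ref %in% tips) setdiff(allTips, tips) else tips
    n <- length(side)
    if (n < 2L || n > length(allTips) - 2L) return(NA_character_)
    paste(sort(side), collapse = "|")
}

# One key per internal node (NA where the node defines no internal split,
# e.g. the root).  Order: node (Ntip+1) .. (Ntip+Nnode).
.nodeBipartitionKeys <- function(phy) {
    nt <- length(phy$tip.label)
    sets <- .nodeTipSets(phy)
    allTips <- phy$tip.label
    vapply(seq_len(phy$Nnode), function(i) {
        tips <- sets[[nt + i]]
        if (length(tips) >= length(allTips)) return(NA_character_)
        .splitKey(tips, allTips)
    }, character(1))
}

# The set of internal bipartition keys of a tree (unrooted reading).
.bipartitionKeys <- function(phy) {
    keys <- .nodeBipartitionKeys(phy)
    sort(unique(keys[!is.na(keys)]))
}

## ---- distances ----

# Distance between cluster profiles from a cluster x gene matrix.
.distanceFromMatrix <- function(M, metric) {
    labs <- rownames(M)
    if (metric %in% c("spearman", "pearson_log", "pearson_sqrt")) {
        X <- switch(metric,
            spearman = M,
            pearson_log = log1p(M),
            pearson_sqrt = sqrt(M))
        const <- apply(X, 1L, function(v) max(v) == min(v))
        if (any(const))
            stop("zero-variance profile under a correlation metric: ",
                 paste(labs[const], collapse = ", "))
        r <- stats::cor(base::t(X),
                        method = if (metric == "spearman") "spearman"
                                 else "pearson")
        d <- 1 - r
    } else if (metric == "euclidean_scaled") {
        Z <- scale(log1p(M))
        Z[, attr(Z, "scaled:scale") == 0] <- 0
        d <- as.matrix(stats::dist(Z))
    } else stop("unknown metric: ", metric)
    d[d < 0 & d > -1e-12] <- 0
    diag(d) <- 0
    dimnames(d) <- list(labs, labs)
    (d + base::t(d)) / 2
}

#' Pairwise expression distances between clusters
#'
#' Distances between per-cluster average expression profiles, restricted to
#' the expressed-gene universe (the "expressed anywhere" union).  Metrics:
#' `"spearman"` (1 - Spearman rank correlation of CPM profiles, the default
#' used for the cell-type tree), `"pearson_log"` (1 - Pearson on
#' `log1p(CPM)`), `"pearson_sqrt"` (1 - Pearson on `sqrt(CPM)`) and
#' `"euclidean_scaled"` (Euclidean on per-gene z-scored `log1p(CPM)`).
#'
#' @param profile a [ClusterProfile-class].
#' @param expressed an [ExpressedGeneSets-class] (its anywhere-union defines
#'   the gene universe), a character vector of genes, or NULL for all genes.
#' @param metric one of the four metrics above.
#' @param exclude cluster labels to drop before computing distances (the
#'   study drops its "undefined" cluster this way).
#' @param restrict optional character vector intersected with the universe,
#'   e.g. a transcription-factor catalogue for a TF-only tree.
#' @return a symmetric non-negative distance matrix with zero diagonal.
#' @examples
#' sim <- simulateAtlas(nClusters = 5, cellsPerCluster = 40, nGenes = 300,
#'                      seed = 2)
#' prof <- clusterProfile(sim$sce)
#' expr <- callExpressed(prof)
#' d <- expressionDistance(prof, expr, metric = "spearman")
#' range(d)
#' @seealso [neighborJoining()], [bootstrapSupports()]
#' @export
expressionDistance <- function(profile, expressed = NULL,
                               metric = c("spearman", "pearson_log",
                                          "pearson_sqrt", "euclidean_scaled"),
                               exclude = character(), restrict = NULL) {
    metric <- match.arg(metric)
    stopifnot(is(profile, "ClusterProfile"))
    M <- meanCPM(profile)
    keep <- setdiff(rownames(M), exclude)
    if (length(keep) < 3L)
        stop("need at least 3 clusters after exclusion")
    universe <- .geneUniverse(profile, expressed, restrict)
    .distanceFromMatrix(M[keep, universe, drop = FALSE], metric)
}

.geneUniverse <- function(profile, expressed, restrict) {
    genes <- colnames(meanCPM(profile))
    universe <- if (is.null(expressed)) genes
        else if (is(expressed, "ExpressedGeneSets")) expressedAnywhere(expressed)
        else as.character(expressed)
    universe <- intersect(universe, genes)
    if (!is.null(restrict)) universe <- intersect(universe, restrict)
    if (length(universe) < 2L)
        stop("gene universe has fewer than 2 genes")
    universe
}

## ---- neighbor joining ----

#' Neighbor-joining tree from a distance matrix
#'
#' Classic Saitou-Nei agglomeration: at each step the pair minimizing
#' `Q(i,j) = (n-2) d(i,j) - r_i - r_j` is joined, branch lengths follow the
#' standard formulas, and distances to the new node are
#' `(d(i,k) + d(j,k) - d(i,j)) / 2`.  Negative branch lengths are clamped to
#' zero with the deficit moved to the sister edge (topology preserving).
#' Ties in Q are broken by the lexicographically smallest pair of
#' representative labels (a subtree is represented by its smallest leaf).
#' On an additive matrix the generating topology and branch lengths are
#' recovered exactly.
#'
#' @param D symmetric non-negative matrix (or `dist`) with zero diagonal and
#'   at least 3 labelled rows.
#' @return a [CellTypeTree-class] (unrooted; no supports).
#' @examples
#' D <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
#'             dimnames = list(LETTERS[1:3], LETTERS[1:3]))
#' tr <- neighborJoining(D)
#' asPhylo(tr)$edge.length   # A:1, B:1, C:3
#' @seealso [bootstrapSupports()], [expressionDistance()]
#' @export
neighborJoining <- function(D) {
    if (inherits(D, "dist")) D <- as.matrix(D)
    if (!is.matrix(D) || nrow(D) != ncol(D))
        stop("validation error: D must be a square matrix")
    if (is.null(rownames(D)))
        stop("validation error: D must have labels")
    if (max(abs(D - base::t(D))) > 1e-8)
        stop("validation error: D must be symmetric")
    if (any(D < 0))
        stop("validation error: D must be non-negative")
    labs <- rownames(D)
    n <- length(labs)
    if (n < 3L) stop("need at least 3 labels")
    fmt <- function(x) sprintf("%.17g", x)
    nwk <- labs
    rep_ <- labs
    d <- unname(D)
    while (n > 3L) {
        r <- rowSums(d)
        Q <- (n - 2) * d - outer(r, r, "+")
        diag(Q) <- Inf
        qmin <- min(Q)
        tol <- 1e-12 * max(1, abs(qmin))
        cand <- which(Q <= qmin + tol, arr.ind = TRUE)
        cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
        key <- vapply(seq_len(nrow(cand)), function(z) {
            pr <- sort(c(rep_[cand[z, 1L]], rep_[cand[z, 2L]]))
            paste(pr, collapse = "\r")
        }, character(1))
        pick <- cand[order(key)[1L], ]
        i <- pick[[1L]]; j <- pick[[2L]]
        vi <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
        vj <- d[i, j] - vi
        if (vi < 0) { vj <- vj + vi; vi <- 0 }
        if (vj < 0) { vi <- max(0, vi + vj); vj <- 0 }
        dn <- (d[i, ] + d[j, ] - d[i, j]) / 2
        merged <- sprintf("(%s:%s,%s:%s)", nwk[i], fmt(vi), nwk[j], fmt(vj))
        keep <- setdiff(seq_len(n), c(i, j))
        d <- rbind(cbind(d[keep, keep, drop = FALSE], dn[keep]),
                   c(dn[keep], 0))
        nwk <- c(nwk[keep], merged)
        rep_ <- c(rep_[keep], min(rep_[c(i, j)]))
        n <- n - 1L
    }
    v1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
    v2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
    v3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
    v1 <- max(0, v1); v2 <- max(0, v2); v3 <- max(0, v3)
    txt <- sprintf("(%s:%s,%s:%s,%s:%s);",
                   nwk[1], fmt(v1), nwk[2], fmt(v2), nwk[3], fmt(v3))
    phy <- ape::read.tree(text = txt)
    .asCellTypeTree(phy, supports = numeric(0))
}

## ---- bootstrap ----

#' Gene-resampling bootstrap supports for the cell-type tree
#'
#' Builds the point-estimate neighbor-joining tree on the full expressed
#' gene universe, then resamples that universe with replacement (same size)
#' `nReps` times, recomputing distances and the NJ tree each time.  The
#' support of each internal bipartition of the point tree is the percentage
#' of replicate trees containing it, rounded to the nearest integer.  The
#' gene universe is fixed once from the full data and then resampled; set
#' `recomputeUniverse = TRUE` to re-apply the expressed filter within every
#' replicate instead.
#'
#' @inheritParams expressionDistance
#' @param nReps number of bootstrap replicates (the study used 10,000).
#' @param seed optional RNG seed for the resampling.
#' @param recomputeUniverse logical; see above.
#' @return a [CellTypeTree-class] whose `supportValues()` map bipartition
#'   keys to integer percentages; the supports are also written into the
#'   tree's internal node labels for Newick export.
#' @examples
#' sim <- simulateAtlas(nClusters = 5, cellsPerCluster = 40, nGenes = 300,
#'                      branchSd = 1, seed = 2)
#' prof <- clusterProfile(sim$sce)
#' tr <- bootstrapSupports(prof, callExpressed(prof), nReps = 50, seed = 9)
#' supportValues(tr)
#' @seealso [neighborJoining()], [writeNewick()]
#' @export
bootstrapSupports <- function(profile, expressed = NULL,
                              metric = c("spearman", "pearson_log",
                                         "pearson_sqrt", "euclidean_scaled"),
                              nReps = 10000, seed = NULL,
                              exclude = character(), restrict = NULL,
                              recomputeUniverse = FALSE) {
    metric <- match.arg(metric)
    if (nReps < 1) stop("parameter error: nReps must be >= 1")
    stopifnot(is(profile, "ClusterProfile"))
    M <- meanCPM(profile)
    keep <- setdiff(rownames(M), exclude)
    if (length(keep) < 3L)
        stop("need at least 3 clusters after exclusion")
    universe <- .geneUniverse(profile, expressed, restrict)
    M0 <- M[keep, universe, drop = FALSE]
    point <- neighborJoining(.distanceFromMatrix(M0, metric))
    keys0 <- .bipartitionKeys(asPhylo(point))
    counts <- setNames(numeric(length(keys0)), keys0)
    thr <- if (is(expressed, "ExpressedGeneSets")) cpmThreshold(expressed)
           else 3
    Mall <- M[keep, , drop = FALSE]
    if (!is.null(restrict))
        Mall <- Mall[, intersect(colnames(Mall), restrict), drop = FALSE]
    if (!is.null(seed)) set.seed(seed)
    for (b in seq_len(nReps)) {
        if (recomputeUniverse) {
            idx <- sample.int(ncol(Mall), replace = TRUE)
            Mb <- Mall[, idx, drop = FALSE]
            Mb <- Mb[, apply(Mb, 2L, max) > thr, drop = FALSE]
        } else {
            idx <- sample.int(ncol(M0), replace = TRUE)
            Mb <- M0[, idx, drop = FALSE]
        }
        tb <- neighborJoining(.distanceFromMatrix(Mb, metric))
        hit <- keys0 %in% .bipartitionKeys(asPhylo(tb))
        counts[hit] <- counts[hit] + 1
    }
    supports <- round(100 * counts / nReps)
    phy <- asPhylo(point)
    nodeKeys <- .nodeBipartitionKeys(phy)
    phy$node.label <- ifelse(is.na(nodeKeys), "",
                             as.character(supports[nodeKeys]))
    new("CellTypeTree", phylo = phy, supports = supports)
}

#' Path-length (patristic) distances of a tree
#'
#' Sums of branch lengths between every pair of leaves; on a tree built from
#' an additive matrix these reproduce the input distances.
#'
#' @param tree a [CellTypeTree-class] or [ape::phylo].
#' @return a symmetric matrix of leaf-to-leaf path lengths.
#' @export
pathDistances <- function(tree) {
    phy <- if (is(tree, "CellTypeTree")) asPhylo(tree) else tree
    d <- ape::cophenetic.phylo(phy)
    d[phy$tip.label, phy$tip.label]
}
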