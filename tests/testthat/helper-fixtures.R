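# Shared fixtures: all built in code at test time.

# ClusterProfile from a raw positive matrix: rows rescaled to CPM.
profileFromRows <- function(M, pct = NULL, n = 10L) {
    cpm <- M / rowSums(M) * 1e6
    if (is.null(pct)) pct <- matrix(0.5, nrow(M), ncol(M), dimnames = dimnames(M))
    new("ClusterProfile", meanCPM = cpm, pctExpressing = pct,
        nCells = stats::setNames(rep(as.integer(n), nrow(M)), rownames(M)))
}

# SingleCellExperiment from a dense count matrix plus labels.
toySCE <- function(counts, clusters, subclusters = clusters) {
    if (is.null(rownames(counts)))
        rownames(counts) <- sprintf("g%d", seq_len(nrow(counts)))
    if (is.null(colnames(counts)))
        colnames(counts) <- sprintf("c%d", seq_len(ncol(counts)))
    SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = as(Matrix::Matrix(counts, sparse = TRUE),
                                  "CsparseMatrix")),
        colData = S4Vectors::DataFrame(cluster = clusters,
                                       subcluster = subclusters,
                                       row.names = colnames(counts)))
}

# Random binary tree plus its additive path-length matrix (the oracle side
# uses ape's own path distances, independent of the package NJ code).
randomAdditive <- function(nLeaves, minLen = 0.1, maxLen = 1) {
    phy <- ape::rtree(nLeaves, rooted = FALSE)
    phy$edge.length <- stats::runif(nrow(phy$edge), minLen, maxLen)
    D <- ape::cophenetic.phylo(phy)
    D <- D[order(rownames(D)), order(colnames(D))]
    list(phy = phy, D = D)
}

# Brute-force two-sided rank-sum p-value by full enumeration of group
# assignments; average ranks computed from first principles (no rank()).
bruteRankSumP <- function(x, y) {
    all <- c(x, y)
    N <- length(all)
    nx <- length(x)
    rnk <- vapply(seq_len(N), function(i)
        sum(all < all[i]) + (sum(all == all[i]) + 1) / 2, numeric(1))
    mu <- nx * (N + 1) / 2
    obs <- abs(sum(rnk[seq_len(nx)]) - mu)
    sel <- utils::combn(N, nx)
    W <- apply(sel, 2L, function(idx) sum(rnk[idx]))
    mean(abs(W - mu) >= obs - 1e-9)
}

# Independent occupancy summaries for swap invariants.
occRowSums <- function(m) as.integer(rowSums(m > 0))
occColSums <- function(m) as.integer(colSums(m > 0))
rowMultisets <- function(m) apply(m, 1L, function(v)
    sort(as.numeric(v[v > 0])), simplify = FALSE)

# Strip dimnames and auxiliary attributes, keep the shape.
bareMatrix <- function(m) {
    a <- as.numeric(m)
    dim(a) <- dim(m)
    a
}
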