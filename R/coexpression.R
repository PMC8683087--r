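# Independent-swap matrix-randomization test: is a gene panel expressed in
# a target subcluster more than expected under an occupancy-margin
# preserving null?

#' Extract the count matrix of one cell family
#'
#' All cells of the family (every subcluster of it), restricted to genes
#' with a nonzero total count within the family.
#'
#' @param x an annotated SingleCellExperiment.
#' @param family cluster label.
#' @return a sparse genes x cells matrix.
#' @seealso [coexpressionTest()]
#' @export
extractSubfamilyMatrix <- function(x, family) {
    m <- .countsOf(x)
    lab <- .clusterLabels(x, "cluster")
    cols <- lab == family
    if (!any(cols)) stop("empty family: ", family)
    sub <- m[, cols, drop = FALSE]
    sub[Matrix::rowSums(sub) > 0, , drop = FALSE]
}

#' Independent-swap randomization of a non-negative matrix
#'
#' Each iteration samples a 2x2 quartet (two distinct rows, two distinct
#' columns) uniformly; when the quartet is an occupancy checkerboard
#' (exactly one diagonal nonzero, the other zero) the two nonzero values
#' are relocated to the empty diagonal along their rows.  The binarized row
#' and column sums, the grand total, and each row's multiset of nonzero
#' values are all conserved; a matrix with no checkerboard (e.g. all
#' entries nonzero) is a fixed point.  By default `nIter` counts attempted
#' swaps, so failed quartets consume an iteration; `countSuccesses = TRUE`
#' instead runs until `nIter` swaps succeeded (capped at `1000 * nIter`
#' attempts).
#'
#' @param m numeric matrix (or sparse Matrix) with non-negative entries, at
#'   least 2 rows and 2 columns.
#' @param nIter number of iterations (the study used 100,000).
#' @param seed optional RNG seed.
#' @param countSuccesses see above.
#' @return a randomized dense matrix with the same dimnames; the attribute
#'   `"swaps"` records the number of successful swaps.
#' @examples
#' m <- matrix(c(5, 0, 0, 7), 2)
#' independentSwap(m, nIter = 100, seed = 1)   # the unique alternative state
#' @export
independentSwap <- function(m, nIter = 100000, seed = NULL,
                            countSuccesses = FALSE) {
    if (nIter < 0) stop("parameter error: nIter must be >= 0")
    x <- as.matrix(m)
    if (any(x < 0)) stop("matrix entries must be non-negative")
    if (nrow(x) < 2L || ncol(x) < 2L)
        stop("need at least 2 rows and 2 columns")
    if (!is.null(seed)) set.seed(seed)
    out <- .independentSwapCpp(x, nIter, countSuccesses)
    dimnames(out) <- dimnames(x)
    out
}

#' Count panel genes expressed in a matrix
#'
#' @param m genes x cells matrix (dense or sparse).
#' @param genes character vector, the panel; genes absent from `m` count as
#'   not expressed.
#' @param rule detection rule: `"any_cell"` (default; at least one nonzero
#'   entry), `"mean_gt0"` (mean over cells > 0, equivalent for non-negative
#'   data) or `"mean_gt_thr"` (mean over cells > `thr`).
#' @param thr threshold for `"mean_gt_thr"`.
#' @return integer count in `[0, length(genes)]`.
#' @export
panelExpressedCount <- function(m, genes,
                                rule = c("any_cell", "mean_gt0",
                                         "mean_gt_thr"),
                                thr = 0) {
    rule <- match.arg(rule)
    genes <- unique(as.character(genes))
    present <- intersect(genes, rownames(m))
    if (!length(present)) return(0L)
    sub <- m[present, , drop = FALSE]
    hit <- switch(rule,
        any_cell = Matrix::rowSums(sub > 0) > 0,
        mean_gt0 = Matrix::rowSums(sub) > 0,
        mean_gt_thr = Matrix::rowSums(sub) / ncol(sub) > thr)
    sum(hit)
}

#' Chi-squared test for a 2x2 contingency table
#'
#' Pearson chi-squared with optional Yates continuity correction (on by
#' default, matching R's own 2x2 default):
#' `chi2 = N (max(0, |ad - bc| - N/2))^2 / (r1 r2 c1 c2)`, with the `N/2`
#' term dropped when `continuity = FALSE`; the p-value comes from the
#' chi-squared distribution with one degree of freedom.  Degenerate tables
#' (a zero row or column margin) return `chi2 = 0`, `p = 1`.
#'
#' @param tab 2x2 matrix of non-negative counts.
#' @param continuity apply the Yates correction?
#' @return list with elements `chi2` and `p`.
#' @examples
#' chiSquared2x2(matrix(c(10, 0, 0, 10), 2))  # chi2 = 16.2
#' @export
chiSquared2x2 <- function(tab, continuity = TRUE) {
    tab <- as.matrix(tab)
    if (!identical(dim(tab), c(2L, 2L))) stop("table must be 2x2")
    if (any(tab < 0)) stop("validation error: negative entries")
    a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
    N <- a + b + c + d
    r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
    if (N == 0 || r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0)
        return(list(chi2 = 0, p = 1))
    dev <- abs(a * d - b * c)
    if (continuity) dev <- max(0, dev - N / 2)
    chi2 <- N * dev^2 / (r1 * r2 * c1 * c2)
    list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

.roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Independent-swap co-expression significance test
#'
#' Tests whether a gene panel is expressed in a target subcluster more than
#' expected by chance.  The family's count matrix is extracted (cells of
#' the whole family, genes with nonzero family total), the observed number
#' `k_obs` of panel genes expressed in the target subcluster's cells is
#' recorded, and the family matrix is then randomized `nReplicates` times
#' with `nSwapIters` independent-swap iterations each (the study used
#' 100,000 iterations looped 500 times), re-counting the panel each time.
#' The mean randomized count, rounded to the closest integer, forms the
#' "randomized" row of a 2x2 expressed / not-expressed contingency table
#' against the observed row, which is tested by [chiSquared2x2()].  Because
#' the chi-squared on the rounded mean discards replicate-to-replicate
#' variance, the empirical permutation p-value
#' `(1 + #\{replicate counts >= k_obs\}) / (nReplicates + 1)` is reported
#' alongside.
#'
#' @param x an annotated SingleCellExperiment with `cluster` and
#'   `subcluster` colData columns.
#' @param family cluster label of the cell family (e.g. the neurons).
#' @param target subcluster label within the family.
#' @param panel character vector of panel gene IDs (non-empty).
#' @param nSwapIters swap iterations per replicate.
#' @param nReplicates number of randomizations.
#' @param rule,thr detection rule, see [panelExpressedCount()].
#' @param continuity Yates correction for the chi-squared.
#' @param seed master seed; each replicate uses an independently drawn
#'   sub-seed so replicates are reproducible and order-independent.
#' @return a [CoexpressionResult-class].
#' @examples
#' sim <- simulateAtlas(nClusters = 4, cellsPerCluster = 60, nGenes = 150,
#'                      panelSize = 10, panelEffect = 25, seed = 5)
#' res <- coexpressionTest(sim$sce, family = sim$truth@panelCluster,
#'                         target = sim$truth@panelTarget,
#'                         panel = panelGeneSet(sim$truth),
#'                         nSwapIters = 2000, nReplicates = 20, seed = 5)
#' res
#' @export
coexpressionTest <- function(x, family, target, panel,
                             nSwapIters = 100000, nReplicates = 500,
                             rule = c("any_cell", "mean_gt0", "mean_gt_thr"),
                             thr = 0, continuity = TRUE, seed = NULL) {
    rule <- match.arg(rule)
    panel <- unique(as.character(panel))
    G <- length(panel)
    if (G == 0L) stop("empty panel")
    if (nReplicates < 1) stop("parameter error: nReplicates must be >= 1")
    fam <- extractSubfamilyMatrix(x, family)
    lab <- .clusterLabels(x, "cluster")
    sub <- .clusterLabels(x, "subcluster")
    targetCells <- colnames(x)[lab == family & sub == target]
    if (!length(targetCells))
        stop("empty target subcluster '", target, "' within family '",
             family, "'")
    famDense <- as.matrix(fam)
    tIdx <- match(targetCells, colnames(famDense))
    kObs <- panelExpressedCount(famDense[, tIdx, drop = FALSE], panel,
                                rule = rule, thr = thr)
    if (!is.null(seed)) set.seed(seed)
    repSeeds <- sample.int(.Machine$integer.max, nReplicates)
    counts <- integer(nReplicates)
    for (r in seq_len(nReplicates)) {
        set.seed(repSeeds[r])
        rand <- .independentSwapCpp(famDense, nSwapIters, FALSE)
        rownames(rand) <- rownames(famDense)
        counts[r] <- panelExpressedCount(rand[, tIdx, drop = FALSE], panel,
                                         rule = rule, thr = thr)
    }
    kMean <- mean(counts)
    kRound <- as.integer(.roundHalfAway(kMean))
    tab <- matrix(c(kObs, G - kObs, kRound, G - kRound), 2, byrow = TRUE,
                  dimnames = list(c("actual", "randomized"),
                                  c("expressed", "not_expressed")))
    chi <- chiSquared2x2(tab, continuity = continuity)
    pEmp <- (1 + sum(counts >= kObs)) / (nReplicates + 1)
    new("CoexpressionResult",
        panel = panel, target = target, G = as.integer(G),
        kObs = as.integer(kObs), kRandMean = kMean, kRandRounded = kRound,
        replicateCounts = counts, table = tab,
        chi2 = chi$chi2, p = chi$p, pEmpirical = pEmp,
        params = list(n_swap_iters = nSwapIters,
                      n_replicates = nReplicates, rule = rule, thr = thr,
                      continuity = continuity, seed = seed,
                      family = family))
}
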