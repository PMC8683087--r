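# Independent-swap null model and the panel co-expression test.

test_that("family extraction keeps the family's cells and nonzero genes", {
    counts <- matrix(0, 4, 10,
                     dimnames = list(paste0("g", 1:4), paste0("c", 1:10)))
    counts[1, ] <- 1
    counts[2, 3:4] <- 5
    # g4 zero inside the family, nonzero outside
    counts[4, 5:10] <- 2
    cl <- rep(c("fam", "other"), c(4, 6))
    sce <- toySCE(counts, cl)
    sub <- extractSubfamilyMatrix(sce, "fam")
    expect_identical(ncol(sub), 4L)
    expect_identical(sort(rownames(sub)), c("g1", "g2"))
    expect_error(extractSubfamilyMatrix(sce, "ghost"), "empty family")
})

test_that("the 2x2 checkerboard has exactly two reachable states", {
    start <- matrix(c(5, 0, 0, 7), 2, byrow = TRUE)
    other <- matrix(c(0, 5, 7, 0), 2, byrow = TRUE)
    # every attempt on a 2x2 checkerboard succeeds, so nIter swaps flip the
    # state nIter times: the chain alternates between exactly two states
    for (s in 1:8) {
        out <- independentSwap(start, nIter = s, seed = s)
        expect_identical(bareMatrix(out),
                         if (s %% 2 == 1) other else start)
    }
    # a successful swap from either state lands in the other
    sw <- bareMatrix(independentSwap(start, nIter = 1000, seed = 1))
    expect_true(identical(sw, start) || identical(sw, other))
})

test_that("matrices without checkerboards are fixed points", {
    m <- matrix(1:12, 3, 4)
    expect_identical(bareMatrix(independentSwap(m, 10000, seed = 2)),
                     matrix(as.numeric(1:12), 3, 4))
    expect_identical(attr(independentSwap(m, 1000, seed = 3), "swaps"), 0)
})

test_that("swap conserves margins, totals and row multisets", {
    set.seed(11)
    for (i in 1:15) {
        m <- matrix(stats::rbinom(20 * 15, 1, 0.3) *
                    stats::rpois(20 * 15, 3), 20, 15)
        out <- independentSwap(m, nIter = 10000, seed = i)
        expect_identical(occRowSums(out), occRowSums(m))
        expect_identical(occColSums(out), occColSums(m))
        expect_equal(sum(out), sum(m))
        expect_identical(rowMultisets(out), rowMultisets(m))
        expect_gt(attr(out, "swaps"), 0)
    }
})

test_that("swap is seed-reproducible and the identity at nIter 0", {
    m <- matrix(stats::rpois(100, 1), 10, 10)
    a <- independentSwap(m, 5000, seed = 42)
    b <- independentSwap(m, 5000, seed = 42)
    expect_identical(a, b)
    expect_identical(bareMatrix(independentSwap(m, 0, seed = 1)),
                     matrix(as.numeric(m), 10, 10))
    expect_error(independentSwap(m, -1), "parameter")
})

test_that("success-counted mode performs the requested number of swaps", {
    m <- rbind(c(1, 0, 2, 0), c(0, 3, 0, 4), c(5, 0, 6, 0))
    out <- independentSwap(m, nIter = 20, seed = 7, countSuccesses = TRUE)
    expect_identical(attr(out, "swaps"), 20)
})

test_that("panel expression counting honours the detection rules", {
    m <- rbind(g1 = c(0, 0), g2 = c(1, 0), g3 = c(4, 8), g4 = c(2, 2))
    expect_identical(panelExpressedCount(m, c("g1", "g2", "g3")), 2L)
    expect_identical(panelExpressedCount(m, c("zz", "yy")), 0L)
    expect_identical(
        panelExpressedCount(m, rownames(m), rule = "mean_gt_thr", thr = 3),
        1L)   # only g3 has mean 6 > 3
    expect_identical(
        panelExpressedCount(m, rownames(m), rule = "mean_gt0"), 3L)
})

test_that("chi-squared matches the closed form and R's own test", {
    res <- chiSquared2x2(matrix(c(10, 0, 0, 10), 2, byrow = TRUE))
    expect_equal(res$chi2, 16.2, tolerance = 1e-12)
    expect_equal(res$p, stats::pchisq(16.2, 1, lower.tail = FALSE))

    expect_equal(chiSquared2x2(matrix(c(5, 5, 5, 5), 2))$chi2, 0)
    expect_equal(chiSquared2x2(matrix(c(5, 5, 5, 5), 2))$p, 1)
    expect_equal(chiSquared2x2(matrix(c(0, 0, 3, 4), 2))$p, 1)  # degenerate
    expect_error(chiSquared2x2(matrix(c(-1, 1, 1, 1), 2)), "negative")

    set.seed(13)
    for (i in 1:50) {
        tab <- matrix(stats::rpois(4, 20) + 1, 2)
        mine <- chiSquared2x2(tab, continuity = TRUE)
        ref <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
        expect_equal(mine$chi2, unname(ref$statistic), tolerance = 1e-10)
        expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
        # without continuity, equals the squared two-proportion z statistic
        m0 <- chiSquared2x2(tab, continuity = FALSE)
        p1 <- tab[1, 1] / sum(tab[1, ]); p2 <- tab[2, 1] / sum(tab[2, ])
        pp <- sum(tab[, 1]) / sum(tab)
        z <- (p1 - p2) / sqrt(pp * (1 - pp) *
                              (1 / sum(tab[1, ]) + 1 / sum(tab[2, ])))
        expect_equal(m0$chi2, z^2, tolerance = 1e-10)
    }
})

test_that("a panel expressed in every cell is a null fixed point", {
    set.seed(17)
    counts <- matrix(stats::rbinom(30 * 20, 1, 0.4) *
                     stats::rpois(30 * 20, 2), 30, 20,
                     dimnames = list(paste0("g", 1:30), paste0("c", 1:20)))
    panel <- paste0("g", 1:5)
    counts[panel, ] <- 3                   # fully occupied rows never move
    cl <- rep("fam", 20)
    sub <- rep(c("fam_s1", "fam_s2"), each = 10)
    sce <- toySCE(counts, cl, sub)
    res <- coexpressionTest(sce, "fam", "fam_s1", panel,
                            nSwapIters = 2000, nReplicates = 10, seed = 3)
    expect_identical(res@kObs, 5L)
    expect_true(all(replicateCounts(res) == 5L))
    expect_equal(res@chi2, 0)
    expect_equal(res@p, 1)
    expect_equal(res@pEmpirical, 1)
})

test_that("a planted panel is detected at the scaled-down design", {
    sim <- simulateAtlas(nClusters = 3, cellsPerCluster = 40, nGenes = 50,
                         markersPerCluster = 0, panelSize = 20,
                         panelEffect = 40, panelBackground = 0.04,
                         panelTargetFrac = 0.15, baselineMean = 0.45,
                         nbDispersion = 2, branchSd = 0.3, seed = 5)
    res <- coexpressionTest(sim$sce, family = sim$truth@panelCluster,
                            target = sim$truth@panelTarget,
                            panel = panelGeneSet(sim$truth),
                            nSwapIters = 10000, nReplicates = 50,
                            seed = 1005)
    expect_lt(res@p, 0.05)
    expect_lte(res@pEmpirical, 0.02)
    expect_gt(res@kObs, res@kRandMean)
    # contingency table wiring
    expect_equal(unname(contingencyTable(res)[1, ]),
                 c(res@kObs, res@G - res@kObs))
    expect_identical(res@kRandRounded,
                     as.integer(floor(res@kRandMean + 0.5)))
})

test_that("test inputs are validated", {
    sim <- simulateAtlas(nClusters = 3, cellsPerCluster = 10, nGenes = 30,
                         markersPerCluster = 0, panelSize = 5, seed = 9)
    expect_error(coexpressionTest(sim$sce, sim$truth@panelCluster,
                                  sim$truth@panelTarget, character(0)),
                 "empty panel")
    expect_error(coexpressionTest(sim$sce, sim$truth@panelCluster,
                                  "no_such_sub", panelGeneSet(sim$truth)),
                 "target")
})
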