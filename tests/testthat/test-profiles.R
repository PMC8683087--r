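# QC filtering, pseudobulk profiles, expressed-gene calling, markers and
# the dotplot table.

test_that("QC filter applies the gene-then-cell rule with strict edges", {
    # g1 in 2 cells (removed at minCells = 3), g2-g4 widespread;
    # cell c5 detects exactly 3 genes after gene removal (retained at
    # minGenes = 3), cell c6 only 2 (removed).
    m <- rbind(
        g1 = c(1, 1, 0, 0, 0, 0),
        g2 = c(1, 1, 1, 1, 1, 1),
        g3 = c(2, 1, 3, 1, 1, 1),
        g4 = c(1, 1, 1, 1, 1, 0))
    colnames(m) <- paste0("c", 1:6)
    out <- filterQC(m, minCells = 3, minGenes = 3)
    expect_identical(rownames(out), c("g2", "g3", "g4"))
    expect_identical(colnames(out), paste0("c", 1:5))
    # idempotence and identity on clean input
    expect_identical(filterQC(out, 3, 3), out)
})

test_that("QC filter warns rather than errors when all cells fail", {
    m <- matrix(1, 3, 3, dimnames = list(paste0("g", 1:3), paste0("c", 1:3)))
    expect_warning(out <- filterQC(m, minCells = 1, minGenes = 10),
                   "every cell")
    expect_identical(ncol(out), 0L)
})

test_that("pseudobulk CPM follows the closed form and is idempotent", {
    m <- matrix(c(3, 1), 2, 1, dimnames = list(c("g1", "g2"), "c1"))
    sce <- toySCE(m, "A")
    prof <- clusterProfile(sce)
    expect_equal(unname(meanCPM(prof)[1, ]), c(750000, 250000))

    m2 <- cbind(c1 = c(3, 1), c2 = c(3, 1))
    rownames(m2) <- c("g1", "g2")
    prof2 <- clusterProfile(toySCE(m2, c("A", "A")))
    expect_equal(meanCPM(prof2), meanCPM(prof))
    expect_equal(unname(rowSums(meanCPM(prof2))), 1e6)
})

test_that("profile recovers the generator's cluster means", {
    # depth ~3000 counts/cell and moderate overdispersion so the largest of
    # 900 per-(gene, cluster) Monte-Carlo errors stays under the 10% bound
    sim <- simulateAtlas(nClusters = 3, cellsPerCluster = 500, nGenes = 300,
                         markersPerCluster = 5, panelSize = 0,
                         baselineMean = 10, nbDispersion = 10, seed = 7)
    prof <- clusterProfile(sim$sce)
    truth <- truthMeans(sim$truth)[rownames(meanCPM(prof)),
                                   colnames(meanCPM(prof))]
    hi <- truth >= 50
    rel <- abs(meanCPM(prof)[hi] - truth[hi]) / truth[hi]
    expect_lt(max(rel), 0.10)
})

test_that("expressed-gene calling is strict and monotone", {
    M <- rbind(A = c(3.0, 3.01, 0, 999993.99),
               B = c(1.0, 0.5, 0, 999998.5))
    colnames(M) <- paste0("g", 1:4)
    prof <- new("ClusterProfile", meanCPM = M,
                pctExpressing = matrix(0.5, 2, 4, dimnames = dimnames(M)),
                nCells = c(A = 5L, B = 5L))
    ex <- callExpressed(prof, threshold = 3)
    expect_false("g1" %in% unlist(geneSets(ex)))   # exactly 3.0 excluded
    expect_true("g2" %in% geneSets(ex)$A)          # 3.01 included
    expect_false("g2" %in% geneSets(ex)$B)
    expect_false("g3" %in% expressedAnywhere(ex))  # all zero
    expect_true("g2" %in% expressedAnywhere(ex))
    # monotone: raising the threshold never adds genes
    ex2 <- callExpressed(prof, threshold = 10)
    expect_true(all(unlist(geneSets(ex2)) %in% unlist(geneSets(ex))))
})

test_that("rank-sum p-values match brute-force enumeration at small n", {
    set.seed(5)
    for (n1 in c(3, 5, 8)) for (n2 in c(3, 6, 10)) {
        x <- sample(0:4, n1, replace = TRUE)   # ties on purpose
        y <- sample(0:4, n2, replace = TRUE) + stats::rbinom(n2, 1, 0.5)
        expect_equal(pluteusAtlas:::.rankSumP(x, y), bruteRankSumP(x, y),
                     tolerance = 1e-12)
    }
    # tie-free case agrees with the exact distribution in wilcox.test
    x <- c(1.2, 3.4, 2.2, 5.1)
    y <- c(0.4, 4.4, 6.2, 0.9, 2.7)
    expect_equal(pluteusAtlas:::.rankSumP(x, y),
                 stats::wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
})

test_that("marker detection honours min.pct and finds planted markers", {
    sim <- simulateAtlas(nClusters = 3, cellsPerCluster = 200, nGenes = 200,
                         markersPerCluster = 8, markerLog2FC = 4,
                         panelSize = 0, seed = 11)
    mk <- findMarkers(sim$sce, "C1")
    planted <- names(markerAssignments(sim$truth))[
        markerAssignments(sim$truth) == "C1"]
    hit <- mk[mk$gene_id %in% planted, ]
    expect_identical(nrow(hit), length(planted))
    expect_true(all(hit$log2_fc > 2))
    expect_true(all(hit$p_adj < 0.01))
    expect_true(all(mk$p_adj >= mk$p))

    # a gene detected in under min.pct of cells in both groups is not tested
    counts <- matrix(5, 4, 210,
                     dimnames = list(paste0("g", 1:4), NULL))
    counts[4, ] <- 0
    counts[4, 1] <- 1                       # ~0.5% both sides
    sce <- toySCE(counts, rep(c("A", "B"), c(105, 105)))
    tab <- findMarkers(sce, "A", minPct = 0.01)
    expect_false("g4" %in% tab$gene_id)

    # groups with identical per-cell compositions: p = 1, log2_fc = 0
    # (g3 detected in the same 3 cells per group so cell totals match)
    eq <- matrix(5, 3, 60, dimnames = list(paste0("g", 1:3), NULL))
    eq[3, ] <- 0
    eq[3, c(1:3, 31:33)] <- 1
    tab2 <- findMarkers(toySCE(eq, rep(c("A", "B"), each = 30)), "A")
    expect_true(all(tab2$p == 1))
    expect_true(all(abs(tab2$log2_fc) < 1e-9))
})

test_that("markers require a minimally sized cluster", {
    counts <- matrix(1:20, 4, 5)
    sce <- toySCE(counts, c("A", "A", "B", "B", "B"))
    expect_error(findMarkers(sce, "A"), "fewer than 3")
})

test_that("dotplot z-scores use the population SD across clusters", {
    # rows already share the same total so CPM scaling keeps "flat" flat
    M <- rbind(A = c(10, 50, 940), B = c(10, 100, 890))
    colnames(M) <- c("flat", "diff", "rest")
    prof <- profileFromRows(M)
    tab <- dotplotTable(prof, c("flat", "diff"))
    zFlat <- tab$scaled_expression[tab$gene_id == "flat"]
    expect_true(all(abs(zFlat) < 1e-9))
    zDiff <- sort(tab$scaled_expression[tab$gene_id == "diff"])
    expect_equal(zDiff, c(-sqrt(0.5), sqrt(0.5)), tolerance = 1e-9)

    expect_warning(tab2 <- dotplotTable(prof, c("flat", "ghost")), "ghost")
    expect_identical(nrow(dotplotTable(prof, character(0))), 0L)
})
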