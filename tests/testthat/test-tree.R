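# Expression distances, neighbor joining, bootstrap supports.

test_that("distance metrics satisfy the basic identities", {
    M <- rbind(A = c(5, 10, 20, 965),
               B = c(5, 10, 20, 965),      # duplicate of A
               C = c(965, 20, 10, 5))      # reversed ranks vs A
    colnames(M) <- paste0("g", 1:4)
    prof <- profileFromRows(M)
    for (met in c("spearman", "pearson_log", "pearson_sqrt",
                  "euclidean_scaled")) {
        d <- expressionDistance(prof, NULL, metric = met)
        expect_equal(unname(diag(d)), rep(0, 3))
        expect_equal(d, t(d))
        expect_equal(d["A", "B"], 0, tolerance = 1e-12)
    }
    dS <- expressionDistance(prof, NULL, metric = "spearman")
    expect_equal(dS["A", "C"], 2, tolerance = 1e-12)   # rho = -1
})

test_that("spearman distance is invariant to monotone transforms", {
    set.seed(1)
    base <- matrix(stats::rexp(4 * 30), 4, 30,
                   dimnames = list(LETTERS[1:4], paste0("g", 1:30)))
    prof1 <- profileFromRows(base)
    base2 <- base
    base2["A", ] <- base["A", ]^3 + 2          # strictly increasing transform
    prof2 <- profileFromRows(base2)
    d1 <- expressionDistance(prof1, NULL, metric = "spearman")
    d2 <- expressionDistance(prof2, NULL, metric = "spearman")
    expect_equal(d1, d2, tolerance = 1e-12)
})

test_that("correlation metrics reject zero-variance profiles by name", {
    M <- rbind(A = c(1, 1, 1), B = c(1, 2, 3), C = c(3, 2, 1))
    colnames(M) <- paste0("g", 1:3)
    prof <- profileFromRows(M)
    expect_error(expressionDistance(prof, NULL, metric = "spearman"), "A")
})

test_that("three-taxon NJ solves the closed form", {
    D <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
                dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
    tr <- neighborJoining(D)
    phy <- asPhylo(tr)
    len <- stats::setNames(phy$edge.length,
                           phy$tip.label[phy$edge[, 2]])
    expect_equal(len[c("A", "B", "C")], c(A = 1, B = 1, C = 3))
})

test_that("NJ is exact on additive matrices and agrees with ape", {
    set.seed(7)
    for (n in c(5, 8, 12)) {
        rt <- randomAdditive(n)
        tr <- neighborJoining(rt$D)
        # topology: same bipartition set as the generating tree
        expect_setequal(bipartitionSets(tr),
                        bipartitionSets(pluteusAtlas:::.asCellTypeTree(rt$phy)))
        # branch lengths: path distances reproduce the input exactly
        pd <- pathDistances(tr)[rownames(rt$D), colnames(rt$D)]
        expect_lt(max(abs(pd - rt$D)), 1e-9)
        # independent cross-check against ape's NJ
        ref <- ape::nj(rt$D)
        expect_equal(ape::dist.topo(ape::unroot(asPhylo(tr)),
                                    ape::unroot(ref)), 0,
                     ignore_attr = TRUE)
    }
})

test_that("NJ validates its input and breaks ties deterministically", {
    D <- matrix(1, 3, 3); diag(D) <- 0
    expect_error(neighborJoining(D), "labels")
    M <- matrix(c(0, 1, 1, 2, 0, 1), 2, 3)
    expect_error(neighborJoining(M), "square")
    Dn <- matrix(c(0, -1, -1, 0), 2,
                 dimnames = list(c("A", "B"), c("A", "B")))
    expect_error(neighborJoining(Dn), "non-negative|at least 3")

    # ultrametric matrix with two equally good first joins: result is
    # deterministic and invariant to input row order
    lab <- c("A", "B", "C", "D")
    D4 <- matrix(4, 4, 4, dimnames = list(lab, lab))
    D4[cbind(c(1, 2), c(2, 1))] <- 2
    D4[cbind(c(3, 4), c(4, 3))] <- 2
    diag(D4) <- 0
    t1 <- neighborJoining(D4)
    perm <- c("D", "B", "A", "C")
    t2 <- neighborJoining(D4[perm, perm])
    expect_setequal(bipartitionSets(t1), bipartitionSets(t2))
    expect_equal(pathDistances(t1)[lab, lab], pathDistances(t2)[lab, lab],
                 tolerance = 1e-12)
})

test_that("duplicate clusters earn full bootstrap support", {
    set.seed(3)
    M <- matrix(stats::rexp(6 * 40, 1 / 100), 6, 40,
                dimnames = list(paste0("K", 1:6), paste0("g", 1:40)))
    M["K6", ] <- M["K5", ]                 # exact duplicate pair
    prof <- profileFromRows(M)
    tr <- bootstrapSupports(prof, NULL, metric = "spearman", nReps = 100,
                            seed = 5)
    cherry <- "K5|K6"
    expect_true(cherry %in% names(supportValues(tr)))
    expect_equal(unname(supportValues(tr)[cherry]), 100)
})

test_that("supports are invariant under cluster label permutation", {
    set.seed(9)
    M <- matrix(stats::rexp(5 * 60, 1 / 50), 5, 60,
                dimnames = list(paste0("K", 1:5), paste0("g", 1:60)))
    prof1 <- profileFromRows(M)
    perm <- c(3, 1, 5, 2, 4)
    prof2 <- profileFromRows(M[perm, ])
    s1 <- supportValues(bootstrapSupports(prof1, NULL, nReps = 60, seed = 2))
    s2 <- supportValues(bootstrapSupports(prof2, NULL, nReps = 60, seed = 2))
    expect_equal(s1[sort(names(s1))], s2[sort(names(s2))])
})

test_that("single-replicate supports are all 0 or 100 and nReps is checked", {
    set.seed(4)
    M <- matrix(stats::rexp(5 * 30), 5, 30,
                dimnames = list(paste0("K", 1:5), paste0("g", 1:30)))
    prof <- profileFromRows(M)
    tr <- bootstrapSupports(prof, NULL, nReps = 1, seed = 1)
    expect_true(all(supportValues(tr) %in% c(0, 100)))
    expect_error(bootstrapSupports(prof, NULL, nReps = 0), "parameter")
})
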