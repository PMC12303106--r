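test_that("gradient splits follow binary levels or the median rule", {
    p <- splitByGradient(c(0, 0, 1, 1))
    expect_identical(p@unitsA, c(1L, 2L))
    expect_identical(p@unitsB, c(3L, 4L))
    expect_identical(p@type, "binary")

    p2 <- splitByGradient(c(1.0, 2.0, 3.0, 4.0))  # median 2.5, ties to A
    expect_identical(p2@unitsA, c(1L, 2L))
    expect_identical(p2@unitsB, c(3L, 4L))
    expect_identical(p2@threshold, 2.5)

    expect_error(splitByGradient(c(5, 5, 5)), "no contrast")
})

test_that("candidate partitions cover the quartiles and degrade gracefully", {
    parts <- gradientPartitions(seq(0, 1, length.out = 100))
    expect_length(parts, 3L)
    expect_true(all(vapply(parts, function(p)
        length(p@unitsA) + length(p@unitsB), 0L) == 100L))
    # binary gradient: one split, no correction partner
    expect_length(gradientPartitions(c(0, 1, 0, 1)), 1L)
    # three distinct values can collapse duplicate thresholds
    expect_lte(length(gradientPartitions(c(1, 2, 2, 2, 3))), 3L)
    expect_error(gradientPartitions(rep(2, 5)), "no contrast")
})

test_that("pair counts condition on discordant units only", {
    # toy 4-unit table: sp1 in units {1,2}, sp2 in units {2,3}
    P <- matrix(0L, 4, 3, dimnames = list(paste0("u", 1:4), c("sp1", "sp2", "sp3")))
    P[c(1, 2), "sp1"] <- 1L
    P[c(2, 3), "sp2"] <- 1L
    part <- new("GradientPartition", unitsA = 1:2, unitsB = 3:4,
        type = "binary", threshold = NA_real_)
    cts <- pairCounts(P, "sp1", "sp2", part)
    expect_identical(cts, list(nA = 1L, n1A = 1L, nB = 1L, n1B = 0L))

    # co-presence everywhere is uninformative
    Q <- matrix(1L, 4, 2, dimnames = list(paste0("u", 1:4), c("a", "b")))
    cq <- pairCounts(Q, "a", "b", part)
    expect_identical(cq$nA + cq$nB, 0L)

    # swapping the pair complements the occurrence counts
    rev <- pairCounts(P, "sp2", "sp1", part)
    expect_identical(rev$nA, cts$nA)
    expect_identical(rev$n1A, cts$nA - cts$n1A)
    expect_identical(rev$n1B, cts$nB - cts$n1B)

    expect_error(pairCounts(P, "sp1", "nope", part), "unknown species")
    expect_error(pairCounts(P, "sp1", "sp1", part), "must differ")
})

test_that("pair p-values match the frozen composite-binomial values", {
    expect_identical(rankConsistencyPvalue(nA = 10, n1A = 5, nB = 10, n1B = 5), 1)
    expect_equal(rankConsistencyPvalue(nA = 10, n1A = 9, nB = 10, n1B = 1),
        2 * 11 / 1024, tolerance = 1e-12)
    expect_equal(rankConsistencyPvalue(nA = 6, n1A = 6, nB = 8, n1B = 0),
        2 * max(1 / 64, 1 / 256), tolerance = 1e-12)
    expect_identical(rankConsistencyPvalue(nA = 0, n1A = 0, nB = 7, n1B = 3), 1)
    expect_error(rankConsistencyPvalue(nA = 5, n1A = -1, nB = 5, n1B = 0),
        "non-negative")
    expect_error(rankConsistencyPvalue(nA = 5, n1A = 6, nB = 5, n1B = 0),
        "exceed")
})

test_that("the pair test is invariant to species and subset relabelling", {
    set.seed(101)
    for (i in 1:100) {
        nA <- sample(0:15, 1); nB <- sample(0:15, 1)
        n1A <- if (nA) sample(0:nA, 1) else 0L
        n1B <- if (nB) sample(0:nB, 1) else 0L
        p <- rankConsistencyPvalue(nA = nA, n1A = n1A, nB = nB, n1B = n1B)
        pSpeciesSwap <- rankConsistencyPvalue(nA = nA, n1A = nA - n1A,
            nB = nB, n1B = nB - n1B)
        pSubsetSwap <- rankConsistencyPvalue(nA = nB, n1A = n1B,
            nB = nA, n1B = n1A)
        expect_equal(p, pSpeciesSwap, tolerance = 1e-12)
        expect_equal(p, pSubsetSwap, tolerance = 1e-12)
    }
})

test_that("evidence is monotone where species 1 is favoured in A*", {
    for (n1B in c(0, 2, 5)) {
        ps <- vapply(6:12, function(n1A)
            rankConsistencyPvalue(nA = 12, n1A = n1A, nB = 12, n1B = n1B), 0)
        expect_true(all(diff(ps) <= 1e-12))
    }
})

test_that("the test is conservative over the whole composite null", {
    # brute-force oracle: exact rejection probability by enumeration of all
    # Binom(nA, qA) x Binom(nB, qB) outcomes, for every (qA, qB) with both
    # probabilities on the same side of 1/2
    pmat <- enumeratePairPvalues(12, 12)
    qs <- seq(0, 0.5, by = 0.1)
    for (qA in qs) for (qB in qs) {
        expect_lte(exactRejectionProb(12, 12, qA, qB, 0.05, pmat), 0.05)
        expect_lte(exactRejectionProb(12, 12, 1 - qA, 1 - qB, 0.05, pmat),
            0.05)
    }
})

test_that("the test has power against a strong rank inconsistency", {
    # qA = 0.95, qB = 0.05, nA = nB = 25: exact rejection probability
    pmat <- enumeratePairPvalues(25, 25)
    expect_gt(exactRejectionProb(25, 25, 0.95, 0.05, 0.05, pmat), 0.99)
})

test_that("the pairwise matrix is symmetric and composes the scalar test", {
    P <- matrix(0L, 8, 3, dimnames = list(paste0("u", 1:8), c("x", "y", "z")))
    P[1:5, "x"] <- 1L
    P[c(2, 3, 6, 7, 8), "y"] <- 1L
    P[c(1, 4, 6, 7, 8), "z"] <- 1L
    part <- new("GradientPartition", unitsA = 1:4, unitsB = 5:8,
        type = "binary", threshold = NA_real_)
    rc <- pairwiseRankTest(P, partition = part, minOccurrences = 1L)
    p <- pvalueMatrix(rc)
    expect_identical(p, t(p))
    expect_identical(unname(diag(p)), rep(1, 3))
    for (i in 1:2) for (j in (i + 1):3) {
        expect_equal(p[i, j],
            rankConsistencyPvalue(pairCounts(P, colnames(P)[i],
                colnames(P)[j], part)),
            tolerance = 1e-12)
    }
})

test_that("the split scan is Bonferroni-bounded by its per-split tests", {
    sim <- neutralSim(n = 60, J = 40, theta = 1, seed = 103)
    rc <- pairwiseRankTest(sim)
    parts <- rc@partitions
    expect_length(parts, 3L)
    P <- presenceMatrix(sim)
    keep <- colSums(P) >= 5
    single <- lapply(parts, function(pt)
        pvalueMatrix(pairwiseRankTest(P[, keep], partition = pt,
            minOccurrences = 5L)))
    bonf <- pmin(3 * Reduce(pmin, single), 1)
    diag(bonf) <- 1
    expect_equal(pvalueMatrix(rc), bonf, tolerance = 1e-12)
})

test_that("rare species are dropped before testing", {
    sim <- neutralSim(n = 50, J = 60, theta = 0.2, seed = 104)
    rc <- pairwiseRankTest(sim, minOccurrences = 5L)
    occ <- colSums(presenceMatrix(sim))
    expect_setequal(retainedSpecies(rc), names(occ)[occ >= 5])
    expect_setequal(droppedSpecies(rc), names(occ)[occ < 5])
    expect_error(pairwiseRankTest(sim, minOccurrences = 1000L),
        "fewer than 2 species")
})

test_that("under neutrality the rejection fraction stays below the level", {
    sim <- neutralSim(n = 100, J = 100, theta = 0.2, seed = 105)
    p <- pvalueMatrix(pairwiseRankTest(sim))
    off <- p[upper.tri(p)]
    expect_lte(mean(off < 0.05), 0.05)
})
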