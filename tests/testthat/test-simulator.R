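test_that("regional pool draws live on the simplex with Dirichlet moments", {
    expect_identical(poolAbundances(sampleRegionalPool(1, 1)), 1)

    nrep <- 1e4
    set.seed(11)
    draws <- replicate(nrep, poolAbundances(sampleRegionalPool(100, 1)))
    expect_true(all(abs(colSums(draws) - 1) < 1e-8))
    # symmetric Dirichlet(1) component mean is 1/J; variance (J-1)/(J^2(J+1))
    se <- sqrt((99 / (100^2 * 101)) / nrep)
    expect_true(all(abs(rowMeans(draws) - 0.01) < 3 * se + 1e-12))

    evenness <- function(p) { p <- p[p > 0]; -sum(p * log(p)) / log(100) }
    set.seed(12)
    evLow <- mean(replicate(1e3,
        evenness(poolAbundances(sampleRegionalPool(100, 0.04)))))
    evHigh <- mean(replicate(1e3,
        evenness(poolAbundances(sampleRegionalPool(100, 1)))))
    expect_lt(evLow, evHigh)

    expect_error(sampleRegionalPool(0, 1), "positive integer")
    expect_error(sampleRegionalPool(10, -1), "positive")
})

test_that("fitness weight follows the Gaussian closed form", {
    expect_identical(fitnessWeight(0.5, 0.5), 1)
    expect_equal(fitnessWeight(0.5, 1.0), exp(-0.25), tolerance = 1e-12)
    expect_equal(fitnessWeight(0.25, 0.0), exp(-0.0625), tolerance = 1e-12)
    # vectorized, and 1 only at the optimum
    tr <- seq(0, 1, by = 0.1)
    w <- fitnessWeight(tr, 0.3)
    expect_true(all(w > 0 & w <= 1))
    expect_identical(which(w == 1), 4L)
    expect_error(fitnessWeight(NA, 1), "finite")
})

test_that("acceptance probability matches hand evaluation and its bounds", {
    expect_identical(
        acceptanceProbability(c(0.2, 0.3, 0.5), rep(0.8, 3), 5, 100), 1)
    expect_identical(acceptanceProbability(c(0.5, 0.5), c(1, 1e-4), 0, 10), 1)
    expect_equal(
        acceptanceProbability(c(0.5, 0.5), c(1.0, 0.5), 1, 2), 0.5625,
        tolerance = 1e-12)
    # always in (0, 1], including extreme exponents handled in log space
    set.seed(21)
    for (i in 1:200) {
        J <- sample(2:6, 1)
        g <- rgamma(J, 1); g <- g / sum(g)
        w <- runif(J, 1e-4, 1)
        p <- acceptanceProbability(g, w, runif(1, 0, 50), sample(1:500, 1))
        expect_gte(p, 0)   # may underflow to 0 in the far tail
        expect_lte(p, 1)   # weighted mean never exceeds the max
    }
    expect_error(acceptanceProbability(numeric(0), numeric(0), 1, 1),
        "non-empty")
    expect_error(acceptanceProbability(c(0.5, 0.5), c(1, -1), 1, 1), "w > 0")
})

test_that("transformed abundances tilt by fitness and stay normalized", {
    g <- c(0.5, 0.5)
    expect_identical(transformRelativeAbundances(g, c(1, 0.5), 0), g)
    expect_equal(transformRelativeAbundances(g, c(1.0, 0.5), 1),
        c(2 / 3, 1 / 3), tolerance = 1e-12)
    set.seed(22)
    for (i in 1:50) {
        J <- sample(2:8, 1)
        gg <- rgamma(J, 1); gg <- gg / sum(gg)
        gt <- transformRelativeAbundances(gg, runif(J, 0.1, 1), runif(1, 0, 20))
        expect_equal(sum(gt), 1, tolerance = 1e-12)
        expect_true(all(gt >= 0))
    }
})

test_that("stationary sampler conserves unit sizes and is seed-deterministic", {
    pool <- sampleRegionalPool(30, theta = 0.5, seed = 31)
    set.seed(32)
    params <- FilteringParams(
        traits = rep(c(0.25, 0.75), 15), optima = runif(20),
        omegaB = 2.77, omegaD = 0, omegaM = 2.77,
        unitSizes = drawUnitSizes(20), immigration = drawImmigration(20))
    for (i in c(1L, 7L, 20L)) {
        x <- sampleStationaryCommunity(i, pool, params, seed = 100 + i)
        expect_identical(sum(x), params@unitSizes[i])
        expect_gte(attr(x, "proposals"), 1L)
    }
    sim1 <- simulateMetacommunity(pool, params, seed = 33)
    sim2 <- simulateMetacommunity(pool, params, seed = 33)
    expect_identical(abundanceMatrix(sim1), abundanceMatrix(sim2))
    expect_identical(rowSums(abundanceMatrix(sim1)),
        setNames(as.double(params@unitSizes), colnames(sim1)))
    # presence is exactly the indicator of positive abundance
    expect_identical(presenceMatrix(sim1), (abundanceMatrix(sim1) > 0) * 1L)
})

test_that("an impossible unit exhausts the proposal budget loudly", {
    pool <- RegionalPool(c(0.999, 0.001))
    params <- FilteringParams(traits = c(1, 0), optima = 0,
        omegaB = 50, omegaD = 0, omegaM = 0,
        unitSizes = 200L, immigration = 5)
    expect_error(
        sampleStationaryCommunity(1, pool, params, maxProposals = 50,
            seed = 41),
        "budget.*sampling unit 1")
})

test_that("neutral draws match the closed-form Dirichlet-multinomial pmf", {
    alpha <- c(1, 2, 2)          # I = 5, pool = (0.2, 0.4, 0.4)
    a <- 5L
    pool <- RegionalPool(c(0.2, 0.4, 0.4))
    params <- FilteringParams(traits = rep(0.5, 3), optima = 0.5,
        unitSizes = a, immigration = 5)
    set.seed(51)
    nrep <- 2e4
    draws <- matrix(0L, nrep, 3)
    for (r in seq_len(nrep))
        draws[r, ] <- sampleStationaryCommunity(1, pool, params)
    comp <- compositions(a, 3L)
    pmf <- apply(comp, 1, dmPmf, alpha = alpha)
    expect_equal(sum(pmf), 1, tolerance = 1e-10)
    key <- apply(comp, 1, paste, collapse = "/")
    obs <- table(factor(apply(draws, 1, paste, collapse = "/"),
        levels = key))
    gof <- suppressWarnings(chisq.test(as.vector(obs), p = pmf))
    expect_gt(gof$p.value, 0.01)
})

test_that("stronger filtering depresses maladapted species, monotonically", {
    # mean relative abundance of the far group under increasing selection
    meanFar <- function(omega, seed) {
        set.seed(seed)
        J <- 40L; n <- 30L
        traits <- rep(c(0.25, 0.75), each = 20L)
        pool <- sampleRegionalPool(J, 1)
        params <- FilteringParams(traits = traits, optima = rep(0.05, n),
            omegaB = omega, omegaD = 0, omegaM = omega,
            unitSizes = rep(100L, n), immigration = rep(5, n))
        A <- abundanceMatrix(simulateMetacommunity(pool, params))
        mean(rowSums(A[, traits == 0.75]) / rowSums(A))
    }
    far <- vapply(c(0, 2.77, 11.98), meanFar, 0, seed = 61)
    expect_true(all(diff(far) < 0))
    expect_lt(far[3], 0.05)   # strong filtering nearly excludes the far group
})

test_that("unit-size and immigration generators honour mean, CV and support", {
    a <- drawUnitSizes(5e3, seed = 71)
    expect_true(all(a >= 1L))
    expect_equal(mean(a), 100, tolerance = 0.03)
    expect_equal(sd(a) / mean(a), 0.25, tolerance = 0.1)
    I <- drawImmigration(5e3, seed = 72)
    expect_true(all(I > 0))
    expect_equal(mean(I), 5, tolerance = 0.03)
    expect_equal(sd(I) / mean(I), 0.25, tolerance = 0.1)
    expect_error(drawUnitSizes(10, mean = 2, cv = 0.25), "overdispersion")
})

test_that("OccurrenceExperiment validates its invariants", {
    P <- matrix(c(1, 0, 1, 1, 0, 0), 3, 2,
        dimnames = list(paste0("u", 1:3), paste0("s", 1:2)))
    oe <- OccurrenceExperiment(presence = P, gradient = c(1, 2, 3))
    expect_s4_class(oe, "OccurrenceExperiment")
    expect_identical(presenceMatrix(oe), P)
    expect_identical(unname(gradientValues(oe)), c(1, 2, 3))
    expect_error(OccurrenceExperiment(presence = P, gradient = 1:2),
        "one value per sampling unit")
    bad <- P; bad[1, 1] <- 2
    expect_error(OccurrenceExperiment(presence = bad, gradient = c(1, 2, 3)),
        "binary")
})
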