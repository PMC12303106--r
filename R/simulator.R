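#' Construct or sample a regional species pool
#'
#' @description
#' `RegionalPool()` wraps a vector of relative abundances;
#' `sampleRegionalPool()` draws one from a symmetric Dirichlet distribution on
#' the J-simplex with evenness parameter `theta` (a larger `theta` yields a
#' more even regional abundance distribution).
#'
#' @param abundances Numeric vector of non-negative relative abundances
#'   summing to one.
#' @param theta Positive Dirichlet evenness parameter.
#' @param J Number of species in the pool.
#' @param seed Optional integer seed.
#' @return A [RegionalPool-class] object.
#' @export
#' @examples
#' sampleRegionalPool(J = 10, theta = 0.2, seed = 1)
RegionalPool <- function(abundances, theta = NA_real_) {
    new("RegionalPool", abundances = as.numeric(abundances),
        theta = as.numeric(theta))
}

#' @rdname RegionalPool
#' @export
sampleRegionalPool <- function(J, theta, seed = NULL) {
    if (length(J) != 1L || !is.finite(J) || J < 1 || J != round(J))
        stop("J must be a single positive integer")
    if (length(theta) != 1L || !is.finite(theta) || theta <= 0)
        stop("theta must be a single positive number")
    setSeedIfGiven(seed)
    if (J == 1) return(RegionalPool(1, theta))
    g <- rgamma(J, shape = theta)
    while (sum(g) == 0) g <- rgamma(J, shape = theta)  # theta << 1 underflow
    RegionalPool(g / sum(g), theta)
}

#' Construct environmental-filtering parameters
#'
#' @param traits Numeric trait value per species.
#' @param optima Numeric optimal trait value per sampling unit (the gradient).
#' @param omegaB,omegaD,omegaM Non-negative selection intensities on birth,
#'   death and immigration.
#' @param unitSizes Integer number of individuals per unit.
#' @param immigration Positive immigration parameter per unit.
#' @param groups Optional integer functional-group label per species.
#' @return A [FilteringParams-class] object.
#' @seealso [drawUnitSizes()], [drawImmigration()] for the stochastic defaults
#'   used by the virtual experiments.
#' @export
FilteringParams <- function(traits, optima, omegaB = 0, omegaD = 0,
        omegaM = 0, unitSizes, immigration, groups = integer(0)) {
    new("FilteringParams", traits = as.numeric(traits),
        optima = as.numeric(optima), omegaB = as.numeric(omegaB),
        omegaD = as.numeric(omegaD), omegaM = as.numeric(omegaM),
        unitSizes = as.integer(unitSizes),
        immigration = as.numeric(immigration), groups = as.integer(groups))
}

#' Gaussian fitness coefficient
#'
#' Fitness of a species with trait `trait` in a unit with optimal trait value
#' `optimum`: \eqn{w = \exp(-(t - t_{opt})^2)}. Equals 1 exactly when the
#' trait sits at the optimum and decays as the trait departs from it.
#'
#' @param trait,optimum Finite numerics (vectorized).
#' @return Fitness value(s) in (0, 1].
#' @export
#' @examples
#' fitnessWeight(0.5, 1.0)  # exp(-0.25)
fitnessWeight <- function(trait, optimum) {
    if (any(!is.finite(trait)) || any(!is.finite(optimum)))
        stop("trait and optimum must be finite")
    exp(-(trait - optimum)^2)
}

#' Acceptance probability of a proposed local composition
#'
#' Probability with which the stationary sampler accepts a Dirichlet proposal
#' g of local relative abundances:
#' \deqn{P_{accept} = \left(\frac{\sum_j g_j w_j^{\Omega_b+\Omega_d}}
#'   {\max_l w_l^{\Omega_b+\Omega_d}}\right)^a.}
#' Computed in log space so that large exponents do not underflow. Equals 1
#' when all fitness values coincide or when `omegaBD` is zero.
#'
#' @param g Relative-abundance vector (sums to one).
#' @param w Strictly positive fitness vector, same length.
#' @param omegaBD Combined selection intensity \eqn{\Omega_b + \Omega_d \ge 0}.
#' @param a Community size (integer >= 1).
#' @return A probability in (0, 1].
#' @export
#' @examples
#' acceptanceProbability(c(0.5, 0.5), c(1.0, 0.5), omegaBD = 1, a = 2) # 0.5625
acceptanceProbability <- function(g, w, omegaBD, a) {
    if (!length(g) || !length(w)) stop("g and w must be non-empty")
    if (length(g) != length(w)) stop("g and w must have equal length")
    if (any(g < 0) || any(w <= 0)) stop("g must be >= 0 and w > 0")
    if (omegaBD < 0 || a < 1) stop("omegaBD must be >= 0 and a >= 1")
    if (omegaBD == 0) return(1)
    x <- omegaBD * log(w)
    s <- sum(g * exp(x - max(x)))
    exp(a * log(s))
}

#' Fitness-transformed local relative abundances
#'
#' Second step of the stationary sampler: tilt an accepted proposal by the
#' fitness weights, \eqn{\tilde g_j = g_j w_j^{\Omega_b+\Omega_d} /
#' \sum_l g_l w_l^{\Omega_b+\Omega_d}}. The identity when `omegaBD` is zero or
#' all fitness values are equal.
#'
#' @inheritParams acceptanceProbability
#' @return A probability vector summing to one.
#' @export
transformRelativeAbundances <- function(g, w, omegaBD) {
    if (length(g) != length(w)) stop("g and w must have equal length")
    if (omegaBD == 0) return(g)
    x <- omegaBD * log(w)
    gt <- g * exp(x - max(x))
    s <- sum(gt)
    if (s == 0) stop("all transformed abundances underflowed to zero")
    gt / s
}

#' Sample one unit's stationary community composition
#'
#' Draws the species abundances of one sampling unit from the stationary
#' distribution of the environmental-filtering jump process, using the
#' three-step construction: (i) propose local relative abundances from a
#' Dirichlet with parameters \eqn{I_i w_{ij}^{\Omega_m} \pi_j} and accept with
#' [acceptanceProbability()]; (ii) tilt the accepted proposal with
#' [transformRelativeAbundances()]; (iii) draw the a(i) individuals from a
#' multinomial with the tilted probabilities. With
#' \eqn{\Omega_b = \Omega_d = 0} or constant traits no rejection is needed and
#' the draw is exactly Dirichlet-multinomial — the spatially implicit neutral
#' prediction.
#'
#' @param unitIndex Which sampling unit (1-based).
#' @param pool A [RegionalPool-class].
#' @param params A [FilteringParams-class].
#' @param maxProposals Rejection budget; exceeding it raises an error naming
#'   the unit and the estimated acceptance rate rather than returning a
#'   biased sample.
#' @param seed Optional integer seed.
#' @return Integer abundance vector of length J summing to the unit's size,
#'   with attribute `"proposals"` giving the number of proposals consumed.
#' @export
sampleStationaryCommunity <- function(unitIndex, pool, params,
        maxProposals = 1e5, seed = NULL) {
    stopifnot(maxProposals >= 1)
    setSeedIfGiven(seed)
    pi <- poolAbundances(pool)
    J <- length(pi)
    if (length(params@traits) != J)
        stop("params traits and pool must agree on the number of species")
    i <- as.integer(unitIndex)
    if (i < 1L || i > length(params@optima)) stop("unknown sampling unit")
    a <- params@unitSizes[i]
    Ii <- params@immigration[i]
    logw <- -(params@traits - params@optima[i])^2  # log fitness, exact form
    omegaBD <- params@omegaB + params@omegaD
    # Dirichlet proposal parameters I_i * w^Omega_m * pi_j, floored to avoid
    # degenerate gamma draws
    alpha <- pmax(Ii * exp(params@omegaM * logw) * pi, 1e-12)
    neutral <- omegaBD == 0 || diff(range(params@traits)) == 0
    proposals <- 0L
    g <- NULL
    if (neutral) {
        repeat {
            proposals <- proposals + 1L
            gg <- rgamma(J, shape = alpha)
            if (sum(gg) > 0) { g <- gg / sum(gg); break }
            if (proposals >= maxProposals)
                stop("degenerate Dirichlet draws in unit ", i)
        }
        gt <- g
    } else {
        x <- omegaBD * logw
        xr <- exp(x - max(x))  # (w / w_max)^(Omega_b + Omega_d)
        chunk <- 16L
        while (is.null(g)) {
            m <- as.integer(min(chunk, maxProposals - proposals))
            if (m < 1L)
                stop(sprintf(paste0("proposal budget (%d) exhausted for ",
                    "sampling unit %d; estimated acceptance rate < %.2g"),
                    as.integer(maxProposals), i, 1 / maxProposals))
            G <- matrix(rgamma(m * J, shape = rep(alpha, each = m)), nrow = m)
            tot <- rowSums(G)
            s <- as.numeric((G %*% xr)) / tot   # weighted mean of xr under g
            pAcc <- ifelse(tot > 0, exp(a * log(s)), 0)
            acc <- which(runif(m) < pAcc)
            if (length(acc)) {
                k <- acc[1L]
                proposals <- proposals + k
                g <- G[k, ] / tot[k]
            } else {
                proposals <- proposals + m
                chunk <- min(chunk * 2L, 1024L)
            }
        }
        gt <- g * xr
        gt <- gt / sum(gt)
    }
    out <- as.integer(rmultinom(1L, size = a, prob = gt))
    attr(out, "proposals") <- proposals
    out
}

#' Simulate a stationary metacommunity sample
#'
#' Loops [sampleStationaryCommunity()] over all sampling units and assembles
#' the result into an [OccurrenceExperiment-class] carrying both the abundance
#' and the presence assay, the unit metadata (gradient = the unit optima, unit
#' sizes, immigration) and the species metadata (traits, groups, pool
#' abundances).
#'
#' @inheritParams sampleStationaryCommunity
#' @return An [OccurrenceExperiment-class]; deterministic given `seed`.
#' @export
#' @examples
#' pool <- sampleRegionalPool(20, theta = 1, seed = 1)
#' par <- FilteringParams(traits = rep(0.5, 20), optima = runif(10),
#'     unitSizes = rep(50L, 10), immigration = rep(5, 10))
#' sim <- simulateMetacommunity(pool, par, seed = 2)
#' rowSums(abundanceMatrix(sim))  # each unit sums to its size
simulateMetacommunity <- function(pool, params, maxProposals = 1e5,
        seed = NULL) {
    setSeedIfGiven(seed)
    n <- length(params@optima)
    J <- length(poolAbundances(pool))
    A <- matrix(0L, nrow = n, ncol = J)
    nprop <- integer(n)
    for (i in seq_len(n)) {
        ai <- sampleStationaryCommunity(i, pool, params,
            maxProposals = maxProposals)
        A[i, ] <- ai
        nprop[i] <- attr(ai, "proposals")
    }
    unitIds <- sprintf("unit%03d", seq_len(n))
    speciesIds <- sprintf("sp%03d", seq_len(J))
    dimnames(A) <- list(unitIds, speciesIds)
    OccurrenceExperiment(
        presence = (A > 0) * 1L,
        gradient = params@optima,
        abundance = A,
        unitData = S4Vectors::DataFrame(
            unitSize = params@unitSizes,
            immigration = params@immigration,
            proposals = nprop,
            row.names = unitIds),
        speciesData = S4Vectors::DataFrame(
            trait = params@traits,
            group = if (length(params@groups)) params@groups
                    else NA_integer_,
            poolAbundance = poolAbundances(pool),
            row.names = speciesIds))
}

#' Construct an OccurrenceExperiment from a units x species table
#'
#' @param presence Binary units x species matrix (rows = sampling units,
#'   columns = species). A non-binary abundance table may be passed instead
#'   via `abundance`, in which case presence is derived as `abundance > 0`.
#' @param gradient Numeric per-unit ecological gradient, length `nrow(presence)`.
#' @param abundance Optional integer units x species abundance matrix.
#' @param unitData,speciesData Optional [S4Vectors::DataFrame] of extra
#'   per-unit / per-species metadata.
#' @return An [OccurrenceExperiment-class].
#' @export
OccurrenceExperiment <- function(presence = NULL, gradient, abundance = NULL,
        unitData = NULL, speciesData = NULL) {
    if (is.null(presence)) {
        if (is.null(abundance)) stop("supply presence and/or abundance")
        presence <- (abundance > 0) * 1L
    }
    presence <- as.matrix(presence)
    if (is.null(rownames(presence)))
        rownames(presence) <- sprintf("unit%03d", seq_len(nrow(presence)))
    if (is.null(colnames(presence)))
        colnames(presence) <- sprintf("sp%03d", seq_len(ncol(presence)))
    if (length(gradient) != nrow(presence))
        stop("gradient must have one value per sampling unit")
    cd <- S4Vectors::DataFrame(gradient = as.numeric(gradient),
        row.names = rownames(presence))
    if (!is.null(unitData)) {
        if (!identical(rownames(unitData), rownames(presence)))
            unitData <- unitData[rownames(presence), , drop = FALSE]
        cd <- cbind(cd, unitData)
    }
    assays <- list(presence = t(presence))
    if (!is.null(abundance)) {
        abundance <- as.matrix(abundance)
        dimnames(abundance) <- dimnames(presence)
        assays$abundance <- t(abundance)
    }
    rd <- if (is.null(speciesData))
        S4Vectors::DataFrame(row.names = colnames(presence))
    else speciesData
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = assays, colData = cd, rowData = rd)
    new("OccurrenceExperiment", se)
}

#' Stochastic unit sizes and immigration rates of the virtual experiments
#'
#' @description
#' `drawUnitSizes()` draws the number of individuals per sampling unit from a
#' negative-binomial distribution with mean 100 and coefficient of variation
#' 0.25 (dispersion r = mu^2 / (sigma^2 - mu) = 10000/525); zero draws are
#' rejected and redrawn, since a unit needs at least one individual for
#' presence data to be meaningful. `drawImmigration()` draws the per-unit
#' immigration parameter from a Gamma distribution with mean 5 and CV 0.25
#' (shape 1/CV^2 = 16, scale 5/16).
#'
#' @param n Number of sampling units.
#' @param mean,cv Mean and coefficient of variation.
#' @param seed Optional integer seed.
#' @return Integer (`drawUnitSizes`) or numeric (`drawImmigration`) vector.
#' @export
drawUnitSizes <- function(n, mean = 100, cv = 0.25, seed = NULL) {
    setSeedIfGiven(seed)
    sigma2 <- (cv * mean)^2
    if (sigma2 <= mean) stop("need overdispersion: cv^2 * mean > 1")
    r <- mean^2 / (sigma2 - mean)
    a <- rnbinom(n, size = r, mu = mean)
    while (any(a == 0L))
        a[a == 0L] <- rnbinom(sum(a == 0L), size = r, mu = mean)
    as.integer(a)
}

#' @rdname drawUnitSizes
#' @export
drawImmigration <- function(n, mean = 5, cv = 0.25, seed = NULL) {
    setSeedIfGiven(seed)
    shape <- 1 / cv^2
    rgamma(n, shape = shape, scale = mean / shape)
}
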