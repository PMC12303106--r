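# Independent oracles and fixture builders used across the suite. Everything
# here is deliberately brute-force: enumeration, closed forms and quadrature
# that do not share code with the implementation they check.

# p-value for every outcome (n1A, n1B) of a pair with nA, nB discordant
# units, computed through the package's scalar interface.
enumeratePairPvalues <- function(nA, nB) {
    outer(0:nA, 0:nB, Vectorize(function(a, b)
        rankConsistencyPvalue(nA = nA, n1A = a, nB = nB, n1B = b)))
}

# Exact rejection probability of the pair test at level alpha when the
# discordant units are independent Bernoulli draws with P(species 1) = qA in
# A* and qB in B*: full enumeration of the bivariate binomial outcome space.
exactRejectionProb <- function(nA, nB, qA, qB, alpha = 0.05,
        pmat = enumeratePairPvalues(nA, nB)) {
    reject <- pmat < alpha
    pa <- dbinom(0:nA, nA, qA)
    pb <- dbinom(0:nB, nB, qB)
    as.numeric(t(pa) %*% reject %*% pb)
}

# Closed-form Dirichlet-multinomial pmf of one composition k (sum a) with
# Dirichlet parameters alpha.
dmPmf <- function(k, alpha) {
    a <- sum(k)
    exp(lgamma(a + 1) - sum(lgamma(k + 1)) +
        lgamma(sum(alpha)) - lgamma(sum(alpha) + a) +
        sum(lgamma(alpha + k) - lgamma(alpha)))
}

# All compositions of a into J non-negative parts, one per row.
compositions <- function(a, J) {
    if (J == 1L) return(matrix(a, 1L, 1L))
    out <- NULL
    for (k in 0:a)
        out <- rbind(out, cbind(k, compositions(a - k, J - 1L)))
    unname(out)
}

# Quadrature oracle for the two-species stationary sampler: pmf of the count
# of species 1 when the proposal is g1 ~ Beta(alpha1, alpha2), the proposal
# is accepted with ((g1 x1 + g2 x2)/max(x))^a and the a individuals are drawn
# from the tilted probabilities. Computed by 1-D numeric integration of
# proposal density x acceptance weight x multinomial kernel.
quadraturePmfJ2 <- function(a, alpha, x) {
    dens <- function(g, k) {
        s <- g * x[1] + (1 - g) * x[2]
        gt <- g * x[1] / s
        dbeta(g, alpha[1], alpha[2]) * (s / max(x))^a *
            choose(a, k) * gt^k * (1 - gt)^(a - k)
    }
    p <- vapply(0:a, function(k)
        integrate(dens, 0, 1, k = k, rel.tol = 1e-10)$value, 0)
    p / sum(p)
}

# Two planted cliques of the given sizes joined by `bridges` random
# inter-clique edges, as an igraph graph with species names.
plantedTwoCliques <- function(size1 = 15L, size2 = 15L, bridges = 1L,
        seed = 1L) {
    g <- igraph::disjoint_union(igraph::make_full_graph(size1),
        igraph::make_full_graph(size2))
    set.seed(seed)
    from <- sample.int(size1, bridges, replace = TRUE)
    to <- size1 + sample.int(size2, bridges, replace = TRUE)
    g <- igraph::add_edges(g, as.vector(rbind(from, to)))
    g <- igraph::simplify(g)
    igraph::V(g)$name <- sprintf("sp%03d", seq_len(size1 + size2))
    g
}

# Small neutral community sample for type-I-error style checks.
neutralSim <- function(n = 100L, J = 100L, theta = 0.2, seed = 1L) {
    set.seed(seed)
    pool <- sampleRegionalPool(J, theta)
    params <- FilteringParams(traits = rep(0.5, J), optima = runif(n),
        unitSizes = drawUnitSizes(n), immigration = drawImmigration(n))
    simulateMetacommunity(pool, params)
}
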