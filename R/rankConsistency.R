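#' Split sampling units into the gradient subsets A* and B*
#'
#' With a binary gradient the two subsets are the two levels (A* = lower
#' level). With a continuous gradient, A* holds the units at or below the
#' global median and B* the rest; ties go to A*. One global split is applied
#' to every species pair so that edges of the rank-consistency network are
#' comparable.
#'
#' @param x An [OccurrenceExperiment-class], or a numeric gradient vector.
#' @return A [GradientPartition-class].
#' @export
#' @examples
#' splitByGradient(c(1, 2, 3, 4))   # A = {1,2}, B = {3,4}
splitByGradient <- function(x) {
    g <- if (is(x, "OccurrenceExperiment")) gradientValues(x) else as.numeric(x)
    if (any(!is.finite(g))) stop("gradient values must be finite")
    lv <- sort(unique(g))
    if (length(lv) < 2L)
        stop("gradient carries no contrast (fewer than 2 distinct values)")
    if (length(lv) == 2L) {
        new("GradientPartition",
            unitsA = which(g == lv[1L]), unitsB = which(g == lv[2L]),
            type = "binary", threshold = NA_real_)
    } else {
        m <- median(g)
        new("GradientPartition",
            unitsA = which(g <= m), unitsB = which(g > m),
            type = "median", threshold = m)
    }
}

#' Discordant-unit counts for one species pair
#'
#' The rank-consistency test conditions on the sampling units where exactly
#' one species of the pair is present (the "discordant" units); units with
#' both or neither species are uninformative and excluded. Within each
#' gradient subset the test only needs how many discordant units there are
#' and in how many of them species 1 (rather than species 2) is the one
#' present.
#'
#' @param x An [OccurrenceExperiment-class] or a binary units x species
#'   matrix.
#' @param sp1,sp2 Species identifiers (column names) or indices; must differ.
#' @param partition A [GradientPartition-class].
#' @return Named list with elements `nA`, `n1A`, `nB`, `n1B`.
#' @export
pairCounts <- function(x, sp1, sp2, partition) {
    P <- if (is(x, "OccurrenceExperiment")) presenceMatrix(x) else as.matrix(x)
    resolve <- function(sp) {
        if (is.character(sp)) {
            j <- match(sp, colnames(P))
            if (is.na(j)) stop("unknown species identifier: ", sp)
            j
        } else as.integer(sp)
    }
    j1 <- resolve(sp1); j2 <- resolve(sp2)
    if (j1 == j2) stop("sp1 and sp2 must differ")
    only1 <- P[, j1] == 1 & P[, j2] == 0
    only2 <- P[, j2] == 1 & P[, j1] == 0
    disc <- only1 | only2
    A <- partition@unitsA; B <- partition@unitsB
    list(nA = sum(disc[A]), n1A = sum(only1[A]),
         nB = sum(disc[B]), n1B = sum(only1[B]))
}

#' Conservative rank-consistency p-value for one species pair
#'
#' @description
#' Under neutrality the presence probabilities of two species are ordered the
#' same way in every sampling unit, so among discordant units the conditional
#' probability q(i) that the present species is species 1 is either at most
#' 1/2 in all units or at least 1/2 in all units (a composite null). Observing
#' species 1 in more than half of the discordant units of one gradient subset
#' and less than half of the other is therefore unlikely, and this is what the
#' test scores.
#'
#' The p-value is distribution-free and conservative: each one-sided
#' configuration is bounded by worst-case Binomial(n, 1/2) tails,
#' \deqn{p_1 = \max\{P(Bin(n_A, 1/2) \ge n_{1A}),\; P(Bin(n_B, 1/2) \le n_{1B})\}}
#' \deqn{p_2 = \max\{P(Bin(n_A, 1/2) \le n_{1A}),\; P(Bin(n_B, 1/2) \ge n_{1B})\}}
#' and the two directions are Bonferroni-combined,
#' \eqn{p = \min(1, 2\min(p_1, p_2))}. A pair with no discordant unit in one
#' of the subsets is untestable and gets p = 1 (only rejections carry
#' information).
#'
#' @param counts List with `nA`, `n1A`, `nB`, `n1B` as from [pairCounts()],
#'   or the four counts given separately.
#' @param nA,n1A,nB,n1B Alternative scalar interface.
#' @return A p-value in [0, 1].
#' @export
#' @examples
#' rankConsistencyPvalue(nA = 10, n1A = 9, nB = 10, n1B = 1)  # ~0.0215
rankConsistencyPvalue <- function(counts = NULL, nA, n1A, nB, n1B) {
    if (!is.null(counts)) {
        nA <- counts$nA; n1A <- counts$n1A
        nB <- counts$nB; n1B <- counts$n1B
    }
    if (any(c(nA, n1A, nB, n1B) < 0)) stop("counts must be non-negative")
    if (n1A > nA || n1B > nB) stop("occurrence counts cannot exceed totals")
    if (nA == 0 || nB == 0) return(1)
    upA <- pbinom(n1A - 1, nA, 0.5, lower.tail = FALSE)  # P(X >= n1A)
    loB <- pbinom(n1B, nB, 0.5)                          # P(X <= n1B)
    loA <- pbinom(n1A, nA, 0.5)
    upB <- pbinom(n1B - 1, nB, 0.5, lower.tail = FALSE)
    p1 <- max(upA, loB)   # species 1 favoured in A*, disfavoured in B*
    p2 <- max(loA, upB)   # the reverse configuration
    min(1, 2 * min(p1, p2))
}

#' Candidate gradient partitions for the split scan
#'
#' A binary gradient admits exactly one split (its two levels). A continuous
#' gradient yields one partition per requested quantile of the gradient
#' distribution (units at or below the threshold go to A*); degenerate or
#' duplicate thresholds are dropped.
#'
#' @param gradient Numeric per-unit gradient.
#' @param quantiles Quantile levels of the candidate thresholds.
#' @return List of [GradientPartition-class] objects.
#' @export
gradientPartitions <- function(gradient, quantiles = c(0.25, 0.5, 0.75)) {
    g <- as.numeric(gradient)
    if (any(!is.finite(g))) stop("gradient values must be finite")
    lv <- sort(unique(g))
    if (length(lv) < 2L)
        stop("gradient carries no contrast (fewer than 2 distinct values)")
    if (length(lv) == 2L)
        return(list(new("GradientPartition",
            unitsA = which(g == lv[1L]), unitsB = which(g == lv[2L]),
            type = "binary", threshold = NA_real_)))
    thr <- unique(as.numeric(quantile(g, quantiles)))
    parts <- lapply(thr, function(th) {
        A <- which(g <= th); B <- which(g > th)
        if (!length(A) || !length(B)) return(NULL)
        new("GradientPartition", unitsA = A, unitsB = B,
            type = "median", threshold = th)
    })
    parts <- parts[!vapply(parts, is.null, TRUE)]
    if (!length(parts)) stop("no valid gradient split at these quantiles")
    parts
}

#' Pairwise rank-consistency tests over all retained species
#'
#' @description
#' Removes species present in fewer than `minOccurrences` sampling units
#' (such species cannot reject a rank-consistency test at the usual levels),
#' then computes the conservative p-value of every remaining species pair.
#'
#' By default the gradient is split at its quartiles (0.25, 0.5, 0.75) and
#' each pair's p-value is the Bonferroni-corrected minimum over the splits:
#' a rank inconsistency reveals itself around the gradient value where the
#' two species' fitness ratio crosses one, and that value need not sit at the
#' median — a lone median split is nearly blind to a species pair whose
#' crossing lies in an outer quartile. The same splits apply to every pair,
#' so edges of the resulting network remain comparable, and the union bound
#' keeps the test distribution-free and conservative. A binary gradient has
#' a single natural split and no correction. Pass an explicit `partition`
#' (or `splitQuantiles = 0.5`) for a single-split analysis.
#'
#' All pair counts are obtained with matrix cross-products, so the cost per
#' split is two dense J' x J' products.
#'
#' @param x An [OccurrenceExperiment-class] or binary units x species matrix.
#' @param partition A [GradientPartition-class] or list of them; by default
#'   computed from the gradient of `x` with [gradientPartitions()].
#' @param minOccurrences Rare-species threshold (default 5).
#' @param splitQuantiles Quantile levels of the candidate splits for a
#'   continuous gradient.
#' @return A [RankConsistencyMatrix-class].
#' @export
#' @examples
#' pool <- sampleRegionalPool(30, theta = 1, seed = 1)
#' par <- FilteringParams(traits = rep(0.5, 30), optima = runif(20),
#'     unitSizes = rep(80L, 20), immigration = rep(5, 20))
#' sim <- simulateMetacommunity(pool, par, seed = 2)
#' rc <- pairwiseRankTest(sim)
#' summary(pvalueMatrix(rc)[upper.tri(pvalueMatrix(rc))])
pairwiseRankTest <- function(x, partition = NULL, minOccurrences = 5L,
        splitQuantiles = c(0.25, 0.5, 0.75)) {
    P <- if (is(x, "OccurrenceExperiment")) presenceMatrix(x) else as.matrix(x)
    if (is.null(partition)) {
        if (!is(x, "OccurrenceExperiment"))
            stop("supply a partition when x is a bare matrix")
        partitions <- gradientPartitions(gradientValues(x), splitQuantiles)
    } else {
        partitions <- if (is(partition, "GradientPartition")) list(partition)
                      else partition
    }
    keep <- colSums(P) >= minOccurrences
    if (sum(keep) < 2L)
        stop("fewer than 2 species retained at minOccurrences = ",
             minOccurrences)
    dropped <- colnames(P)[!keep]
    P <- P[, keep, drop = FALSE]
    storage.mode(P) <- "double"
    p <- matrix(1, ncol(P), ncol(P))
    for (part in partitions)
        p <- pmin(p, singleSplitPvalues(P, part))
    p <- pmin(length(partitions) * p, 1)   # Bonferroni over the splits
    diag(p) <- 1
    dimnames(p) <- list(colnames(P), colnames(P))
    new("RankConsistencyMatrix", pvalues = p, partitions = partitions,
        minOccurrences = as.integer(minOccurrences), dropped = dropped)
}

# Matrix of single-split composite-binomial p-values for all pairs; P is a
# numeric binary units x species matrix.
singleSplitPvalues <- function(P, partition) {
    PA <- P[partition@unitsA, , drop = FALSE]
    PB <- P[partition@unitsB, , drop = FALSE]
    # onlyA[j,k] = number of units in A* where j is present and k absent
    onlyA <- crossprod(PA, 1 - PA)
    onlyB <- crossprod(PB, 1 - PB)
    n1A <- onlyA; nAm <- onlyA + t(onlyA)
    n1B <- onlyB; nBm <- onlyB + t(onlyB)
    upA <- pbinom(n1A - 1, nAm, 0.5, lower.tail = FALSE)
    loB <- pbinom(n1B, nBm, 0.5)
    loA <- pbinom(n1A, nAm, 0.5)
    upB <- pbinom(n1B - 1, nBm, 0.5, lower.tail = FALSE)
    p <- pmin(2 * pmin(pmax(upA, loB), pmax(loA, upB)), 1)
    p[nAm == 0 | nBm == 0] <- 1
    p
}
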