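#' Assign functional groups and trait values
#'
#' Each of the J species is independently and uniformly assigned one of the F
#' functional groups; its trait equals the group's value. Group trait values
#' are 0.5 for F = 1, (0.25, 0.75) for F = 2 and (0, 0.5, 1) for F = 3, so
#' that groups are evenly spread over the [0, 1] gradient of unit optima.
#'
#' @param J Number of species.
#' @param F Number of functional groups (1, 2 or 3).
#' @param seed Optional integer seed.
#' @return List with `traits` (numeric length J) and `groups` (integer
#'   length J).
#' @export
assignGroupsAndTraits <- function(J, F, seed = NULL) {
    values <- switch(as.character(F),
        "1" = 0.5, "2" = c(0.25, 0.75), "3" = c(0, 0.5, 1),
        stop("F must be 1, 2 or 3"))
    setSeedIfGiven(seed)
    groups <- sample.int(F, J, replace = TRUE)
    list(traits = values[groups], groups = groups)
}

#' Factorial design grid of the virtual experiments
#'
#' Enumerates the full crossing of number of sampling units, regional-pool
#' evenness, number of functional groups and filtering intensity, with a
#' fixed number of replicate datasets per cell and one child seed per
#' dataset. The default values give the 3 x 3 x 3 x 3 x 30 = 2430-dataset
#' design of the full study; `replicates` is the knob for reduced-scale runs.
#'
#' @param nValues Numbers of sampling units.
#' @param thetaValues Regional-pool evenness values.
#' @param FValues Numbers of functional groups.
#' @param omegaValues Filtering intensities (0 = neutral).
#' @param replicates Datasets per cell (default 30).
#' @param baseSeed Base seed from which one child seed per dataset is
#'   spawned.
#' @return Data frame with one row per dataset: `n`, `theta`, `F`, `omega`,
#'   `replicate`, `seed`.
#' @export
#' @examples
#' nrow(designGrid())  # 2430
designGrid <- function(nValues = c(50L, 100L, 200L),
        thetaValues = c(0.04, 0.2, 1), FValues = 1:3,
        omegaValues = c(0, 2.77, 11.98), replicates = 30L, baseSeed = 1L) {
    g <- expand.grid(replicate = seq_len(replicates), omega = omegaValues,
        F = FValues, theta = thetaValues, n = nValues,
        KEEP.OUT.ATTRS = FALSE)
    g <- g[, c("n", "theta", "F", "omega", "replicate")]
    g$seed <- spawnSeeds(baseSeed, nrow(g))
    g
}

#' Simulate and analyse one virtual dataset
#'
#' One cell replicate of the virtual experiment: sample a regional pool,
#' assign groups and traits, draw unit optima (uniform on [0, 1] — these are
#' the ecological gradient), unit sizes and immigration rates, simulate the
#' stationary metacommunity with filtering on birth and immigration
#' (\eqn{\Omega_b = \Omega_m = \Omega}, \eqn{\Omega_d = 0}), then run the
#' full detection pipeline: rare-species filter, pairwise rank-consistency
#' tests with a median split on the gradient, consistency graph at `alpha`,
#' one Leiden run, module count, and (when at least two modules are found and
#' the trait varies) the pruned trait classification tree.
#'
#' @param n Number of sampling units.
#' @param theta Regional-pool evenness.
#' @param F Number of functional groups.
#' @param omega Filtering intensity (applied to birth and immigration).
#' @param seed Integer seed for the whole replicate.
#' @param J Regional-pool species richness (default 100).
#' @param minOccurrences Rare-species threshold (default 5).
#' @param alpha Edge threshold of the consistency graph (default 0.05).
#' @param fitTree Fit the trait tree when >= 2 modules are detected?
#' @return One-row data frame: the cell parameters, `seed`, `richness`
#'   (retained species), `nModules` (modules of size >= 2),
#'   `treeSignificant` (logical, NA when no tree was fitted) and `error`
#'   (NA or the failure message; failures are recorded, not dropped).
#' @export
simulateAndDetect <- function(n, theta, F, omega, seed, J = 100L,
        minOccurrences = 5L, alpha = 0.05, fitTree = TRUE) {
    rec <- data.frame(n = n, theta = theta, F = F, omega = omega,
        seed = seed, richness = NA_integer_, nModules = NA_integer_,
        treeSignificant = NA, error = NA_character_,
        stringsAsFactors = FALSE)
    res <- try({
        set.seed(as.integer(seed))
        pool <- sampleRegionalPool(J, theta)
        ag <- assignGroupsAndTraits(J, F)
        params <- FilteringParams(traits = ag$traits, optima = runif(n),
            omegaB = omega, omegaD = 0, omegaM = omega,
            unitSizes = drawUnitSizes(n), immigration = drawImmigration(n),
            groups = ag$groups)
        sim <- simulateMetacommunity(pool, params)
        rc <- pairwiseRankTest(sim, minOccurrences = minOccurrences)
        graph <- buildConsistencyGraph(rc, alpha = alpha)
        mem <- detectModules(graph)
        rec$richness <- length(mem)
        rec$nModules <- countEffectiveModules(mem)
        if (fitTree && rec$nModules >= 2L && F >= 2L) {
            # discriminate the counted modules: singletons are not modules
            keep <- mem %in% as.integer(names(which(table(mem) >= 2L)))
            tr <- speciesTraits(sim)[names(mem)[keep]]
            tree <- fitModuleTree(tr, mem[keep])
            rec$treeSignificant <- isSignificant(tree)
        }
        NULL
    }, silent = TRUE)
    if (inherits(res, "try-error"))
        rec$error <- conditionMessage(attr(res, "condition"))
    rec
}

#' Run (part of) the factorial virtual experiment
#'
#' Applies [simulateAndDetect()] to every row of a design grid. Records are
#' independent given their seeds, so any execution order yields identical
#' output.
#'
#' @param grid Data frame as returned by [designGrid()] (possibly subset).
#' @param ... Passed on to [simulateAndDetect()] (`J`, `alpha`, ...).
#' @param verbose Print a progress line every 25 datasets?
#' @return Data frame of records, one row per dataset.
#' @export
runExperiment <- function(grid, ..., verbose = FALSE) {
    out <- vector("list", nrow(grid))
    for (k in seq_len(nrow(grid))) {
        out[[k]] <- simulateAndDetect(grid$n[k], grid$theta[k], grid$F[k],
            grid$omega[k], grid$seed[k], ...)
        if (verbose && k %% 25L == 0L)
            message("  ", k, "/", nrow(grid), " datasets done")
    }
    do.call(rbind, out)
}

#' Detection-performance summaries of experiment records
#'
#' Aggregates a record table into the quantities the virtual study reports:
#' the per-cell distribution of detected module counts, and the grid-level
#' rates — probability of recovering exactly F modules and at least two
#' modules among non-neutral datasets, the false-positive rate among neutral
#' datasets (F = 1 or \eqn{\Omega = 0}), and the trait-tree significance
#' rates among correctly resolved datasets.
#'
#' @param records Data frame from [runExperiment()].
#' @return List with elements `cellTable` (cell x module-count frequencies),
#'   `rates` (named numeric vector of grid-level percentages) and `counts`
#'   (the denominators behind each rate).
#' @export
summarizeDetection <- function(records) {
    if (!nrow(records)) stop("no records to summarize")
    ok <- !is.na(records$nModules)
    r <- records[ok, , drop = FALSE]
    neutral <- r$F == 1 | r$omega == 0
    cellTable <- as.data.frame(table(
        n = r$n, theta = r$theta, F = r$F, omega = r$omega,
        nModules = r$nModules))
    cellTable <- cellTable[cellTable$Freq > 0, ]
    pct <- function(x) 100 * mean(x)
    sel2 <- !neutral & r$F == 2
    sel3 <- !neutral & r$F == 3
    tree2 <- sel2 & r$nModules == 2 & !is.na(r$treeSignificant)
    tree3 <- sel3 & r$nModules == 3 & !is.na(r$treeSignificant)
    rates <- c(
        neutralOneModule = if (any(neutral)) pct(r$nModules[neutral] == 1)
                           else NA_real_,
        falsePositive = if (any(neutral)) pct(r$nModules[neutral] >= 2)
                        else NA_real_,
        F2exact = if (any(sel2)) pct(r$nModules[sel2] == 2) else NA_real_,
        F3atLeast2 = if (any(sel3)) pct(r$nModules[sel3] >= 2) else NA_real_,
        F3exact = if (any(sel3)) pct(r$nModules[sel3] == 3) else NA_real_,
        treeF2 = if (any(tree2)) pct(r$treeSignificant[tree2]) else NA_real_,
        treeF3 = if (any(tree3)) pct(r$treeSignificant[tree3]) else NA_real_)
    counts <- c(neutral = sum(neutral), F2 = sum(sel2), F3 = sum(sel3),
        treeF2 = sum(tree2), treeF3 = sum(tree3),
        failed = sum(!ok))
    list(cellTable = cellTable, rates = rates, counts = counts)
}
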