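#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData rowData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats pbinom rbinom rgamma rmultinom runif median rnbinom
#'   predict quantile chisq.test rbeta complete.cases setNames
#' @importFrom utils read.csv write.csv head
NULL

#' Regional species pool
#'
#' An infinite regional pool with fixed species relative abundances
#' \eqn{\pi_1, \ldots, \pi_J}. All local sampling units draw immigrants from
#' this common pool; under neutrality the pool abundances are the only source
#' of among-species differences in local presence probability.
#'
#' @slot abundances Numeric vector of relative abundances, non-negative and
#'   summing to one.
#' @slot theta Numeric scalar, the symmetric Dirichlet evenness parameter used
#'   to draw the pool (larger values give a more even pool). \code{NA} when
#'   the pool was supplied directly rather than sampled.
#'
#' @seealso [sampleRegionalPool()]
#' @exportClass RegionalPool
setClass("RegionalPool",
    representation(abundances = "numeric", theta = "numeric"),
    prototype(abundances = numeric(0), theta = NA_real_))

setValidity("RegionalPool", function(object) {
    pi <- object@abundances
    if (length(pi) < 1L)
        return("pool must contain at least one species")
    if (any(!is.finite(pi)) || any(pi < 0))
        return("relative abundances must be finite and non-negative")
    if (abs(sum(pi) - 1) > 1e-8)
        return("relative abundances must sum to 1")
    if (!is.na(object@theta) && object@theta <= 0)
        return("theta must be positive")
    TRUE
})

#' Environmental-filtering parameters
#'
#' Full parameterization of the spatially implicit environmental-filtering
#' metacommunity model: each species j carries a trait \eqn{t_j}, each sampling
#' unit i an optimal trait value \eqn{t_{opt}(i)}, and the fitness coefficient
#' \eqn{w_{ij} = \exp(-(t_j - t_{opt}(i))^2)} tilts per-capita birth, death and
#' immigration rates with intensities \eqn{\Omega_b}, \eqn{\Omega_d},
#' \eqn{\Omega_m}. With all intensities zero, or constant traits, the model is
#' neutral and local composition is Dirichlet-multinomial.
#'
#' @slot traits Numeric vector, one trait value per species.
#' @slot optima Numeric vector, one optimal trait value per sampling unit;
#'   this is also the ecological gradient of the virtual experiments.
#' @slot omegaB,omegaD,omegaM Non-negative selection intensities on the birth,
#'   death and immigration rates.
#' @slot unitSizes Integer vector, number of individuals per sampling unit
#'   (each at least 1).
#' @slot immigration Positive numeric vector, immigration parameter
#'   \eqn{I_i} per unit.
#' @slot groups Optional integer vector of functional-group labels per species
#'   (zero length when absent).
#'
#' @seealso [FilteringParams()], [simulateMetacommunity()]
#' @exportClass FilteringParams
setClass("FilteringParams",
    representation(traits = "numeric", optima = "numeric",
        omegaB = "numeric", omegaD = "numeric", omegaM = "numeric",
        unitSizes = "integer", immigration = "numeric", groups = "integer"))

setValidity("FilteringParams", function(object) {
    n <- length(object@optima)
    if (n < 1L) return("at least one sampling unit is required")
    if (length(object@unitSizes) != n || length(object@immigration) != n)
        return("optima, unitSizes and immigration must have equal length n")
    if (length(object@traits) < 1L) return("traits must cover >= 1 species")
    if (length(object@groups) && length(object@groups) != length(object@traits))
        return("groups must be empty or one label per species")
    for (s in c("omegaB", "omegaD", "omegaM")) {
        v <- slot(object, s)
        if (length(v) != 1L || !is.finite(v) || v < 0)
            return(sprintf("%s must be a single non-negative number", s))
    }
    if (any(object@unitSizes < 1L)) return("unit sizes must be >= 1")
    if (any(object@immigration <= 0)) return("immigration must be positive")
    if (any(!is.finite(object@traits)) || any(!is.finite(object@optima)))
        return("traits and optima must be finite")
    TRUE
})

#' Presence-absence community data with an ecological gradient
#'
#' The central data container: a [SummarizedExperiment::SummarizedExperiment]
#' whose rows are species and whose columns are sampling units, with a
#' mandatory \code{"presence"} assay (binary) and, for simulated data, an
#' \code{"abundance"} assay of individual counts. The per-unit ecological
#' gradient lives in \code{colData(x)$gradient}; species traits, group labels
#' and pool abundances live in \code{rowData}.
#'
#' Note the orientation: the ecology convention writes occurrence tables as
#' units x species, and the accessors [presenceMatrix()] and
#' [abundanceMatrix()] return that orientation, while the underlying assays
#' follow the Bioconductor features-in-rows convention.
#'
#' @seealso [OccurrenceExperiment()], [simulateMetacommunity()]
#' @exportClass OccurrenceExperiment
setClass("OccurrenceExperiment",
    contains = "SummarizedExperiment")

setValidity("OccurrenceExperiment", function(object) {
    anames <- SummarizedExperiment::assayNames(object)
    if (!("presence" %in% anames))
        return("an OccurrenceExperiment needs a 'presence' assay")
    P <- SummarizedExperiment::assay(object, "presence")
    if (!all(P %in% c(0, 1)))
        return("presence assay must be binary (0/1)")
    if (!("gradient" %in% names(SummarizedExperiment::colData(object))))
        return("colData must contain a 'gradient' column")
    if ("abundance" %in% anames) {
        A <- SummarizedExperiment::assay(object, "abundance")
        if (any(A < 0) || any(A != round(A)))
            return("abundance assay must hold non-negative integers")
        if (!identical((A > 0) * 1, P * 1))
            return("presence must be the indicator of abundance > 0")
    }
    if (anyDuplicated(rownames(object)) || anyDuplicated(colnames(object)))
        return("species and unit identifiers must be unique")
    TRUE
})

#' Gradient split of sampling units
#'
#' A partition of the sampling units into the two disjoint subsets A* and B*
#' that the rank-consistency test contrasts: for a binary gradient the two
#' levels, for a continuous gradient the units at or below the global median
#' (A*) versus the rest (B*).
#'
#' @slot unitsA,unitsB Integer indices of the units in each subset.
#' @slot type Either \code{"binary"} or \code{"median"}.
#' @slot threshold The median used for a continuous split (\code{NA} for a
#'   binary gradient).
#'
#' @seealso [splitByGradient()]
#' @exportClass GradientPartition
setClass("GradientPartition",
    representation(unitsA = "integer", unitsB = "integer",
        type = "character", threshold = "numeric"))

setValidity("GradientPartition", function(object) {
    if (length(object@unitsA) < 1L || length(object@unitsB) < 1L)
        return("both subsets must be non-empty")
    if (length(intersect(object@unitsA, object@unitsB)))
        return("subsets A* and B* must be disjoint")
    if (!object@type %in% c("binary", "median"))
        return("type must be 'binary' or 'median'")
    TRUE
})

#' Pairwise rank-consistency test results
#'
#' Holds the symmetric matrix of rank-consistency p-values over all retained
#' species pairs, together with the gradient partition used and the
#' rare-species filter applied.
#'
#' @slot pvalues Symmetric numeric matrix with unit diagonal, dimnames the
#'   retained species identifiers.
#' @slot partitions List of [GradientPartition-class] objects the tests
#'   conditioned on; the p-values are Bonferroni-corrected for their number.
#' @slot minOccurrences Rare-species threshold: species present in fewer
#'   units were removed before testing.
#' @slot dropped Identifiers of the removed species.
#'
#' @seealso [pairwiseRankTest()], [buildConsistencyGraph()]
#' @exportClass RankConsistencyMatrix
setClass("RankConsistencyMatrix",
    representation(pvalues = "matrix", partitions = "list",
        minOccurrences = "integer", dropped = "character"))

setValidity("RankConsistencyMatrix", function(object) {
    p <- object@pvalues
    if (nrow(p) != ncol(p)) return("p-value matrix must be square")
    if (nrow(p) < 2L) return("need at least two retained species")
    if (is.null(rownames(p)) || !identical(rownames(p), colnames(p)))
        return("p-value matrix needs matching species dimnames")
    if (any(p < 0 | p > 1, na.rm = TRUE)) return("p-values must lie in [0,1]")
    if (max(abs(p - t(p))) > 1e-12) return("p-value matrix must be symmetric")
    if (!length(object@partitions) ||
        !all(vapply(object@partitions, is, TRUE, "GradientPartition")))
        return("partitions must be a non-empty list of GradientPartition")
    TRUE
})

#' Consensus module structure
#'
#' The result of replicated stochastic module detection: a reference
#' membership, the pairwise co-assignment frequencies across runs, and the
#' robust cores (maximal groups of species placed in the same module in every
#' run). Species belonging to no core of size two or more are "unassigned".
#'
#' @slot membership Named integer vector, the module label of each species in
#'   the reference (first) run.
#' @slot coassignment Symmetric numeric matrix of co-assignment frequencies
#'   in [0, 1] with unit diagonal.
#' @slot cores List of character vectors, the robust module cores.
#' @slot unassigned Character vector of species in no core.
#' @slot nRuns Number of detection runs performed.
#'
#' @seealso [consensusCores()], [detectModules()]
#' @exportClass ModuleConsensus
setClass("ModuleConsensus",
    representation(membership = "integer", coassignment = "matrix",
        cores = "list", unassigned = "character", nRuns = "integer"))

setValidity("ModuleConsensus", function(object) {
    sp <- names(object@membership)
    if (is.null(sp)) return("membership must be named by species")
    if (!identical(rownames(object@coassignment), sp))
        return("coassignment dimnames must match membership names")
    allCore <- unlist(object@cores, use.names = FALSE)
    if (anyDuplicated(allCore)) return("cores must be disjoint")
    if (!all(c(allCore, object@unassigned) %in% sp))
        return("cores and unassigned must be subsets of the species set")
    TRUE
})

#' Pruned classification tree of module membership on traits
#'
#' A CART-style tree predicting the module of each species from its traits,
#' grown fully and then cost-complexity pruned with the one-standard-error
#' rule on 10-fold cross-validation. The tree is "significant" when its
#' splits lower the cross-validated classification error clearly beyond the
#' noise of the CV estimate (see [fitModuleTree()] for the exact rule); a
#' significant tree always retains at least one split after pruning.
#'
#' @slot tree The fully grown \code{rpart} object.
#' @slot pruned The pruned \code{rpart} object.
#' @slot cvPath Data frame: the cost-complexity table (CP, nsplit, rel error,
#'   xerror, xstd).
#' @slot significant Logical, \code{TRUE} when the CV error drop is
#'   significant.
#' @slot droppedSpecies Number of species removed for missing trait values.
#'
#' @seealso [fitModuleTree()]
#' @exportClass ModuleTraitTree
setClass("ModuleTraitTree",
    representation(tree = "ANY", pruned = "ANY", cvPath = "data.frame",
        significant = "logical", droppedSpecies = "integer"))
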