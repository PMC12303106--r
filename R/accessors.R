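#' @rdname RegionalPool-class
#' @aliases poolAbundances,RegionalPool-method
setMethod("poolAbundances", "RegionalPool", function(x) x@abundances)

#' @rdname RegionalPool-class
#' @aliases poolTheta,RegionalPool-method
setMethod("poolTheta", "RegionalPool", function(x) x@theta)

setMethod("show", "RegionalPool", function(object) {
    pi <- object@abundances
    cat("RegionalPool with", length(pi), "species\n")
    cat("  theta:", ifelse(is.na(object@theta), "(not sampled)",
        format(object@theta)), "\n")
    cat("  evenness (Shannon/log J):",
        format(round(shannonEvenness(pi), 3)), "\n")
})

setMethod("show", "FilteringParams", function(object) {
    cat("FilteringParams:", length(object@traits), "species x",
        length(object@optima), "sampling units\n")
    cat(sprintf("  omega (b, d, m): %g, %g, %g\n",
        object@omegaB, object@omegaD, object@omegaM))
    cat("  unit sizes:", paste(range(object@unitSizes), collapse = "-"),
        " immigration mean:", format(round(mean(object@immigration), 2)), "\n")
    if (length(object@groups))
        cat("  functional groups:", length(unique(object@groups)), "\n")
})

#' @rdname OccurrenceExperiment-class
#' @aliases presenceMatrix,OccurrenceExperiment-method
setMethod("presenceMatrix", "OccurrenceExperiment", function(x)
    t(SummarizedExperiment::assay(x, "presence")))

#' @rdname OccurrenceExperiment-class
#' @aliases abundanceMatrix,OccurrenceExperiment-method
setMethod("abundanceMatrix", "OccurrenceExperiment", function(x) {
    if (!"abundance" %in% SummarizedExperiment::assayNames(x))
        stop("this OccurrenceExperiment carries no abundance assay")
    t(SummarizedExperiment::assay(x, "abundance"))
})

#' @rdname OccurrenceExperiment-class
#' @aliases gradientValues,OccurrenceExperiment-method
setMethod("gradientValues", "OccurrenceExperiment", function(x) {
    g <- SummarizedExperiment::colData(x)$gradient
    names(g) <- colnames(x)
    g
})

#' @rdname OccurrenceExperiment-class
#' @aliases speciesTraits,OccurrenceExperiment-method
setMethod("speciesTraits", "OccurrenceExperiment", function(x) {
    rd <- SummarizedExperiment::rowData(x)
    if (!"trait" %in% names(rd)) return(NULL)
    tr <- rd$trait
    names(tr) <- rownames(x)
    tr
})

#' @rdname OccurrenceExperiment-class
#' @aliases groupLabels,OccurrenceExperiment-method
setMethod("groupLabels", "OccurrenceExperiment", function(x) {
    rd <- SummarizedExperiment::rowData(x)
    if (!"group" %in% names(rd)) return(NULL)
    g <- rd$group
    names(g) <- rownames(x)
    g
})

setMethod("show", "GradientPartition", function(object) {
    cat("GradientPartition (", object@type, " split): |A*| = ",
        length(object@unitsA), ", |B*| = ", length(object@unitsB),
        sep = "")
    if (!is.na(object@threshold))
        cat(", threshold = ", format(object@threshold), sep = "")
    cat("\n")
})

#' @rdname RankConsistencyMatrix-class
#' @aliases pvalueMatrix,RankConsistencyMatrix-method
setMethod("pvalueMatrix", "RankConsistencyMatrix", function(x) x@pvalues)

#' @rdname RankConsistencyMatrix-class
#' @aliases retainedSpecies,RankConsistencyMatrix-method
setMethod("retainedSpecies", "RankConsistencyMatrix",
    function(x) rownames(x@pvalues))

#' @rdname RankConsistencyMatrix-class
#' @aliases droppedSpecies,RankConsistencyMatrix-method
setMethod("droppedSpecies", "RankConsistencyMatrix", function(x) x@dropped)

setMethod("show", "RankConsistencyMatrix", function(object) {
    p <- object@pvalues
    off <- p[upper.tri(p)]
    cat("RankConsistencyMatrix:", nrow(p), "retained species (",
        length(object@dropped), "dropped below",
        object@minOccurrences, "occurrences )\n")
    cat("  gradient splits scanned:", length(object@partitions),
        "( Bonferroni-corrected )\n")
    cat("  pairs with p < 0.05:", sum(off < 0.05), "/", length(off), "\n")
})

#' @rdname ModuleConsensus-class
#' @aliases moduleMembership,ModuleConsensus-method
setMethod("moduleMembership", "ModuleConsensus", function(x) x@membership)

#' @rdname ModuleConsensus-class
#' @aliases moduleCores,ModuleConsensus-method
setMethod("moduleCores", "ModuleConsensus", function(x) x@cores)

#' @rdname ModuleConsensus-class
#' @aliases coassignmentMatrix,ModuleConsensus-method
setMethod("coassignmentMatrix", "ModuleConsensus", function(x) x@coassignment)

#' @rdname ModuleConsensus-class
#' @aliases unassignedSpecies,ModuleConsensus-method
setMethod("unassignedSpecies", "ModuleConsensus", function(x) x@unassigned)

setMethod("show", "ModuleConsensus", function(object) {
    cat("ModuleConsensus over", object@nRuns, "runs:",
        length(object@cores), "robust cores of sizes",
        paste(vapply(object@cores, length, 1L), collapse = ", "), "\n")
    cat("  unassigned species:", length(object@unassigned), "\n")
})

#' @rdname ModuleTraitTree-class
#' @aliases isSignificant,ModuleTraitTree-method
setMethod("isSignificant", "ModuleTraitTree", function(x) x@significant)

#' @rdname ModuleTraitTree-class
#' @aliases cvPath,ModuleTraitTree-method
setMethod("cvPath", "ModuleTraitTree", function(x) x@cvPath)

setMethod("show", "ModuleTraitTree", function(object) {
    ns <- sum(object@pruned$frame$var != "<leaf>")
    cat("ModuleTraitTree:", ns, "split(s) after 1-SE pruning;",
        if (object@significant) "significant" else "not significant", "\n")
    if (object@droppedSpecies > 0L)
        cat("  species dropped for missing traits:",
            object@droppedSpecies, "\n")
})
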