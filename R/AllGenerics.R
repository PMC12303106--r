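#' @rdname RegionalPool-class
#' @param x A \code{RegionalPool}.
#' @export
setGeneric("poolAbundances", function(x) standardGeneric("poolAbundances"))

#' @rdname RegionalPool-class
#' @export
setGeneric("poolTheta", function(x) standardGeneric("poolTheta"))

#' @rdname OccurrenceExperiment-class
#' @param x An \code{OccurrenceExperiment}.
#' @export
setGeneric("presenceMatrix", function(x) standardGeneric("presenceMatrix"))

#' @rdname OccurrenceExperiment-class
#' @export
setGeneric("abundanceMatrix", function(x) standardGeneric("abundanceMatrix"))

#' @rdname OccurrenceExperiment-class
#' @export
setGeneric("gradientValues", function(x) standardGeneric("gradientValues"))

#' @rdname OccurrenceExperiment-class
#' @export
setGeneric("speciesTraits", function(x) standardGeneric("speciesTraits"))

#' @rdname OccurrenceExperiment-class
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))

#' @rdname RankConsistencyMatrix-class
#' @param x A \code{RankConsistencyMatrix}.
#' @export
setGeneric("pvalueMatrix", function(x) standardGeneric("pvalueMatrix"))

#' @rdname RankConsistencyMatrix-class
#' @export
setGeneric("retainedSpecies", function(x) standardGeneric("retainedSpecies"))

#' @rdname RankConsistencyMatrix-class
#' @export
setGeneric("droppedSpecies", function(x) standardGeneric("droppedSpecies"))

#' @rdname ModuleConsensus-class
#' @param x A \code{ModuleConsensus}.
#' @export
setGeneric("moduleMembership", function(x) standardGeneric("moduleMembership"))

#' @rdname ModuleConsensus-class
#' @export
setGeneric("moduleCores", function(x) standardGeneric("moduleCores"))

#' @rdname ModuleConsensus-class
#' @export
setGeneric("coassignmentMatrix",
    function(x) standardGeneric("coassignmentMatrix"))

#' @rdname ModuleConsensus-class
#' @export
setGeneric("unassignedSpecies",
    function(x) standardGeneric("unassignedSpecies"))

#' @rdname ModuleTraitTree-class
#' @param x A \code{ModuleTraitTree}.
#' @export
setGeneric("isSignificant", function(x) standardGeneric("isSignificant"))

#' @rdname ModuleTraitTree-class
#' @export
setGeneric("cvPath", function(x) standardGeneric("cvPath"))
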