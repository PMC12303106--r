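#' Build the rank-consistency network
#'
#' Species are the nodes; two species are connected when their
#' rank-consistency test is \emph{not} rejected at level `alpha`
#' (p >= alpha). Modules of this graph are neutral species clusters: species
#' co-occur neutrally within a module but not with species outside it.
#'
#' @param x A [RankConsistencyMatrix-class] or a symmetric p-value matrix
#'   with species dimnames.
#' @param alpha Edge threshold in (0, 1), default 0.05.
#' @return An [igraph::igraph] simple undirected graph.
#' @export
buildConsistencyGraph <- function(x, alpha = 0.05) {
    if (length(alpha) != 1L || !is.finite(alpha) || alpha <= 0 || alpha >= 1)
        stop("alpha must lie strictly between 0 and 1")
    p <- if (is(x, "RankConsistencyMatrix")) pvalueMatrix(x) else as.matrix(x)
    if (nrow(p) != ncol(p) || max(abs(p - t(p))) > 1e-8)
        stop("p-value matrix must be square and symmetric")
    adj <- (p >= alpha) * 1
    diag(adj) <- 0
    igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
        diag = FALSE)
}

#' Detect modules with the Leiden algorithm
#'
#' One run of Leiden community detection on the unweighted graph, using the
#' modularity objective at resolution 1. Isolated nodes come out as
#' singletons. The algorithm is stochastic; fix `seed` for a reproducible
#' partition, and see [consensusCores()] for aggregating many runs.
#'
#' @param graph An igraph graph (from [buildConsistencyGraph()]).
#' @param seed Optional integer seed.
#' @param resolution Resolution parameter of the modularity objective.
#' @return Named integer vector: module label per species.
#' @export
detectModules <- function(graph, seed = NULL, resolution = 1) {
    if (igraph::vcount(graph) < 1L) stop("graph must contain >= 1 node")
    setSeedIfGiven(seed)
    cl <- igraph::cluster_leiden(graph, objective_function = "modularity",
        resolution = resolution, n_iterations = 3L)
    m <- igraph::membership(cl)
    out <- as.integer(m)
    names(out) <- igraph::V(graph)$name
    out
}

#' Count modules of size two or more
#'
#' Singleton modules are ignored: a lone species carries no co-occurrence
#' signal, and a fully neutral community is read as "one single large
#' module".
#'
#' @param membership Named module-label vector as from [detectModules()].
#' @return Integer count of modules containing at least two species.
#' @export
countEffectiveModules <- function(membership) {
    if (!length(membership)) return(0L)
    sum(table(membership) >= 2L)
}

#' Robust module cores over replicated Leiden runs
#'
#' Runs [detectModules()] `nRuns` times with distinct child seeds, computes
#' the pairwise co-assignment frequency matrix, and defines the robust cores
#' as the connected components (of size >= 2) of the graph whose edges are
#' the species pairs co-assigned in every single run. Species in no such
#' component are reported as unassigned: the stochastic algorithm does not
#' place them consistently.
#'
#' @param graph An igraph graph (from [buildConsistencyGraph()]).
#' @param nRuns Number of detection runs (default 500, >= 2).
#' @param seed Optional base seed; child seeds are spawned with
#'   [spawnSeeds()].
#' @param resolution Passed on to [detectModules()].
#' @return A [ModuleConsensus-class].
#' @export
consensusCores <- function(graph, nRuns = 500L, seed = NULL, resolution = 1) {
    if (nRuns < 2L) stop("nRuns must be >= 2")
    sp <- igraph::V(graph)$name
    J <- length(sp)
    seeds <- if (is.null(seed)) sample.int(.Machine$integer.max - 1L, nRuns)
             else spawnSeeds(seed, nRuns)
    co <- matrix(0, J, J, dimnames = list(sp, sp))
    reference <- NULL
    for (r in seq_len(nRuns)) {
        m <- detectModules(graph, seed = seeds[r], resolution = resolution)
        if (r == 1L) reference <- m
        co <- co + outer(m, m, "==")
    }
    co <- co / nRuns
    always <- co >= 1 - 1e-12
    diag(always) <- FALSE
    coreGraph <- igraph::graph_from_adjacency_matrix(always * 1,
        mode = "undirected", diag = FALSE)
    comp <- igraph::components(coreGraph)
    cores <- split(sp, comp$membership)
    cores <- unname(cores[vapply(cores, length, 1L) >= 2L])
    unassigned <- setdiff(sp, unlist(cores, use.names = FALSE))
    new("ModuleConsensus", membership = reference, coassignment = co,
        cores = cores, unassigned = unassigned, nRuns = as.integer(nRuns))
}
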