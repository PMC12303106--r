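#' Read a presence-absence table from CSV
#'
#' Expects a comma-separated file with a header row of species identifiers
#' and a first column of sampling-unit identifiers (units as rows — the
#' ecology convention). Abundance-valued inputs are thresholded at > 0 with a
#' warning.
#'
#' @param path Path to the CSV file.
#' @param gradient Optional numeric gradient (else attach one later or read
#'   it with [readGradientCsv()]).
#' @return If `gradient` is given, an [OccurrenceExperiment-class]; otherwise
#'   the binary units x species matrix.
#' @export
readPresenceCsv <- function(path, gradient = NULL) {
    df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 2L || nrow(df) < 1L) stop("empty or degenerate table: ", path)
    ids <- as.character(df[[1L]])
    sp <- colnames(df)[-1L]
    if (anyDuplicated(ids))
        stop("duplicate unit identifiers: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    if (anyDuplicated(sp))
        stop("duplicate species columns: ",
             paste(unique(sp[duplicated(sp)]), collapse = ", "))
    M <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(M)) stop("non-numeric entries in presence table: ", path)
    if (any(is.na(M))) stop("missing values in presence table: ", path)
    if (any(M < 0)) stop("negative entries in presence table: ", path)
    if (any(!M %in% c(0, 1))) {
        warning("abundance-valued input thresholded at > 0 to presence")
        M <- (M > 0) * 1
    }
    dimnames(M) <- list(ids, sp)
    if (is.null(gradient)) return(M)
    OccurrenceExperiment(presence = M, gradient = gradient)
}

#' Read a per-unit gradient from CSV
#'
#' Two columns: unit identifier, gradient value. Values are aligned to the
#' unit identifiers of `units` (row order in the file is irrelevant). A
#' binary character gradient (two levels) is mapped to 0/1 in level order
#' with a message.
#'
#' @param path Path to the CSV file.
#' @param units Character vector of expected unit identifiers (e.g.
#'   `rownames(presenceMatrix(x))`).
#' @return Named numeric vector aligned with `units`.
#' @export
readGradientCsv <- function(path, units) {
    df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stop("gradient file needs (unit_id, value) columns")
    ids <- as.character(df[[1L]])
    v <- df[[2L]]
    if (!is.numeric(v)) {
        lv <- sort(unique(as.character(v)))
        if (length(lv) != 2L)
            stop("non-numeric gradient with ", length(lv),
                 " levels; only binary character gradients are mapped")
        message("binary gradient levels mapped: ", lv[1L], " -> 0, ",
                lv[2L], " -> 1")
        v <- as.numeric(match(as.character(v), lv) - 1L)
    }
    missing <- setdiff(units, ids)
    if (length(missing))
        stop("gradient missing for unit(s): ",
             paste(missing, collapse = ", "))
    extra <- setdiff(ids, units)
    if (length(extra))
        stop("gradient lists unknown unit(s): ",
             paste(extra, collapse = ", "))
    out <- as.numeric(v[match(units, ids)])
    names(out) <- units
    out
}

#' Read a species-trait table from CSV
#'
#' First column: species identifier; remaining columns: traits (numeric or
#' categorical). Rows are aligned to `species`; missing species raise an
#' error, extra species are dropped with a message.
#'
#' @param path Path to the CSV file.
#' @param species Character vector of expected species identifiers.
#' @return Data frame of traits with rownames `species`.
#' @export
readTraitsCsv <- function(path, species) {
    df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stop("trait file needs (species_id, trait...) columns")
    ids <- as.character(df[[1L]])
    if (anyDuplicated(ids))
        stop("duplicate species in trait table: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    missing <- setdiff(species, ids)
    if (length(missing))
        stop("traits missing for species: ", paste(missing, collapse = ", "))
    extra <- setdiff(ids, species)
    if (length(extra))
        message(length(extra), " species in trait table not in the data; ",
                "dropped")
    out <- df[match(species, ids), -1L, drop = FALSE]
    rownames(out) <- species
    out
}

#' Write a simulated metacommunity to CSV files
#'
#' Writes four files into `dir`: `abundance.csv` and `presence.csv`
#' (units x species with identifiers), `units.csv` (per-unit gradient, size,
#' immigration) and `species.csv` (trait, group, pool abundance).
#'
#' @param x An [OccurrenceExperiment-class] from [simulateMetacommunity()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
writeMetacommunityCsv <- function(x, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- file.path(dir,
        c("abundance.csv", "presence.csv", "units.csv", "species.csv"))
    writeMat <- function(M, path) {
        df <- data.frame(unit_id = rownames(M), M, check.names = FALSE)
        write.csv(df, path, row.names = FALSE)
    }
    if ("abundance" %in% SummarizedExperiment::assayNames(x))
        writeMat(abundanceMatrix(x), paths[1L])
    writeMat(presenceMatrix(x), paths[2L])
    cd <- as.data.frame(SummarizedExperiment::colData(x))
    write.csv(data.frame(unit_id = colnames(x), cd, check.names = FALSE),
        paths[3L], row.names = FALSE)
    rd <- as.data.frame(SummarizedExperiment::rowData(x))
    write.csv(data.frame(species_id = rownames(x), rd, check.names = FALSE),
        paths[4L], row.names = FALSE)
    invisible(paths)
}

#' Write a rank-consistency p-value matrix to CSV
#'
#' @param x A [RankConsistencyMatrix-class] or plain symmetric matrix.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
writePvalueCsv <- function(x, path) {
    p <- if (is(x, "RankConsistencyMatrix")) pvalueMatrix(x) else x
    df <- data.frame(species_id = rownames(p), p, check.names = FALSE)
    write.csv(df, path, row.names = FALSE)
    invisible(path)
}

#' Generate an on-disk test fixture with known ground truth
#'
#' A thin wrapper over the simulator that writes a complete small dataset
#' (presence, gradient and trait CSVs) of one of three kinds: `"neutral"`
#' (one functional group), `"two_groups"` or `"three_groups"` (strong
#' filtering, \eqn{\Omega = 11.98}). Same seed, same bytes.
#'
#' @param kind One of `"neutral"`, `"two_groups"`, `"three_groups"`.
#' @param dir Output directory.
#' @param n,J Numbers of sampling units and pool species.
#' @param theta Regional-pool evenness.
#' @param seed Integer seed.
#' @return Invisibly, a list with the file paths and the simulated
#'   [OccurrenceExperiment-class].
#' @export
makeFixture <- function(kind = c("neutral", "two_groups", "three_groups"),
        dir, n = 100L, J = 100L, theta = 1, seed = 1L) {
    kind <- match.arg(kind)
    F <- switch(kind, neutral = 1L, two_groups = 2L, three_groups = 3L)
    omega <- if (F == 1L) 0 else 11.98
    set.seed(as.integer(seed))
    pool <- sampleRegionalPool(J, theta)
    ag <- assignGroupsAndTraits(J, F)
    params <- FilteringParams(traits = ag$traits, optima = runif(n),
        omegaB = omega, omegaD = 0, omegaM = omega,
        unitSizes = drawUnitSizes(n), immigration = drawImmigration(n),
        groups = ag$groups)
    sim <- simulateMetacommunity(pool, params)
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- writeMetacommunityCsv(sim, dir)
    gpath <- file.path(dir, "gradient.csv")
    write.csv(data.frame(unit_id = colnames(sim),
        gradient = gradientValues(sim)), gpath, row.names = FALSE)
    tpath <- file.path(dir, "traits.csv")
    write.csv(data.frame(species_id = rownames(sim),
        trait = speciesTraits(sim), group = groupLabels(sim)),
        tpath, row.names = FALSE)
    invisible(list(paths = c(paths, gradient = gpath, traits = tpath),
        experiment = sim, kind = kind, seed = seed))
}
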