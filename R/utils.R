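#' Spawn reproducible child seeds from a base seed
#'
#' Every stochastic step of a multi-dataset workflow gets its own child seed
#' so that any single dataset can be re-simulated in isolation. The spawning
#' rule is fixed: seed the R generator with \code{baseSeed} and draw \code{n}
#' integers without replacement from \code{1 .. .Machine$integer.max - 1}.
#'
#' @param baseSeed Single integer.
#' @param n Number of child seeds.
#' @return Integer vector of length \code{n}.
#' @export
#' @examples
#' spawnSeeds(1L, 3L)
spawnSeeds <- function(baseSeed, n) {
    stopifnot(length(baseSeed) == 1L, is.finite(baseSeed), n >= 1L)
    old <- globalenv()$.Random.seed
    on.exit(restoreSeed(old))
    set.seed(as.integer(baseSeed))
    sample.int(.Machine$integer.max - 1L, n)
}

restoreSeed <- function(old) {
    if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv())
    } else {
        assign(".Random.seed", old, envir = globalenv())
    }
    invisible(NULL)
}

# Shannon evenness H / log(S) of a relative-abundance vector.
shannonEvenness <- function(p) {
    p <- p[p > 0]
    if (length(p) <= 1L) return(0)
    -sum(p * log(p)) / log(length(p))
}

# set.seed only when a seed is supplied; NULL leaves the RNG stream alone.
setSeedIfGiven <- function(seed) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    invisible(NULL)
}
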