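#' Classification tree of module membership on species traits
#'
#' Fits a CART-style binary recursive-partitioning tree (Gini impurity,
#' via \pkg{rpart}) predicting each species' module from its traits, grows it
#' fully (complexity penalty 0), and prunes it back with the
#' one-standard-error rule on the 10-fold cross-validated cost-complexity
#' path: the retained tree is the smallest whose cross-validated error lies
#' within one SE of the minimum.
#'
#' The tree is declared \emph{significant} when the splits produce a drop in
#' cross-validated classification error that clearly exceeds its noise: the
#' root's CV error minus its SE must exceed the best subtree's CV error plus
#' two of its SEs. The extra margin absorbs the selection bias of taking a
#' minimum over the whole cost-complexity path (a fully grown path offers
#' many subtrees, and with a handful it is easy for one to undercut the root
#' by chance); under random module labels the rule stays below a 10 percent
#' false-significance rate while clean trait structure is always detected.
#' A significant tree always retains at least one split after pruning; the
#' converse need not hold.
#'
#' Species with missing trait values are dropped (their number is recorded),
#' and categorical traits are handled natively by CART's subset splits.
#'
#' @param traits Data frame (or named numeric vector, taken as a single
#'   trait) of species traits, rows named by species.
#' @param membership Named module-label vector (from [detectModules()] or a
#'   [ModuleConsensus-class] reference partition); at least two distinct
#'   modules are required among species with trait data.
#' @param seed Optional integer seed (the cross-validation folds are random).
#' @param xval Number of cross-validation folds (default 10).
#' @param minsplit Minimum node size to attempt a split. The default 5 suits
#'   species-level data (tens of rows): a floor of 20 would forbid any split
#'   in species-poor datasets; overfitting is controlled by pruning instead.
#' @return A [ModuleTraitTree-class].
#' @export
#' @examples
#' tr <- data.frame(trait = rep(c(0.25, 0.75), each = 20),
#'     row.names = sprintf("sp%02d", 1:40))
#' mem <- setNames(rep(1:2, each = 20), rownames(tr))
#' fitModuleTree(tr, mem, seed = 1)
fitModuleTree <- function(traits, membership, seed = NULL, xval = 10L,
        minsplit = 5L) {
    if (is.null(dim(traits)))
        traits <- data.frame(trait = traits,
            row.names = names(traits), check.names = FALSE)
    traits <- as.data.frame(traits)
    common <- intersect(rownames(traits), names(membership))
    if (!length(common))
        stop("traits and membership share no species identifiers")
    df <- traits[common, , drop = FALSE]
    df$.module <- factor(membership[common])
    complete <- stats::complete.cases(df)
    nDropped <- sum(!complete)
    df <- df[complete, , drop = FALSE]
    if (nlevels(droplevels(df$.module)) < 2L)
        stop("nothing to discriminate: fewer than 2 modules with trait data")
    df$.module <- droplevels(df$.module)
    setSeedIfGiven(seed)
    fit <- rpart::rpart(.module ~ ., data = df, method = "class",
        control = rpart::rpart.control(cp = 0, xval = xval,
            minsplit = minsplit))
    cp <- as.data.frame(fit$cptable)
    # 1-SE rule: smallest tree with xerror within one SE of the minimum
    best <- which.min(cp$xerror)
    thr <- cp$xerror[best] + cp$xstd[best]
    chosen <- min(which(cp$xerror <= thr))
    pruned <- rpart::prune(fit, cp = cp$CP[chosen] + 1e-12)
    # significant CV drop from the root, with a margin against the
    # minimum-selection bias of the grown path
    significant <- (cp$xerror[1L] - cp$xstd[1L]) >
        (cp$xerror[best] + 2 * cp$xstd[best])
    new("ModuleTraitTree", tree = fit, pruned = pruned, cvPath = cp,
        significant = significant, droppedSpecies = as.integer(nDropped))
}

#' Module-by-trait composition tables
#'
#' For each trait, a contingency table of trait values (numeric traits are
#' tabulated by their distinct values) against module labels — the direct way
#' to read which kinds of species each module collects.
#'
#' @param membership Named module-label vector.
#' @param traits Data frame of species traits, rows named by species (a named
#'   vector is taken as a single trait).
#' @return Named list of contingency tables, one per trait column.
#' @export
describeModuleComposition <- function(membership, traits) {
    if (is.null(dim(traits)))
        traits <- data.frame(trait = traits,
            row.names = names(traits), check.names = FALSE)
    traits <- as.data.frame(traits)
    common <- intersect(rownames(traits), names(membership))
    if (!length(common))
        stop("traits and membership share no species identifiers")
    mod <- factor(membership[common])
    out <- lapply(traits[common, , drop = FALSE], function(v)
        table(trait = v, module = mod, useNA = "no"))
    names(out) <- colnames(traits)
    out
}
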