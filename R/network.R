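#' Build an absolute-Pearson co-expression network over a region subset
#'
#' Each edge weight is the absolute value of the Pearson correlation of two
#' genes' region-level expression profiles across the chosen regions. Genes
#' with zero variance over the subset get all their edges set to 0 (with a
#' warning) so that rankings remain total.
#'
#' @param regionExpr a [RegionExpression-class].
#' @param subset character vector of region labels (default: all regions);
#'   must contain at least 3 regions.
#' @return A [CorrelationNetwork-class].
#' @examples
#' re <- RegionExpression(matrix(rnorm(40), 8, 5,
#'           dimnames = list(paste0("g", 1:8), paste0("r", 1:5))),
#'       structureHigh = rep("cerebrum", 5))
#' net <- buildNetwork(re)
#' @export
buildNetwork <- function(regionExpr, subset = NULL) {
    if (is.null(subset)) subset <- regionLabels(regionExpr)
    missing <- setdiff(subset, regionLabels(regionExpr))
    if (length(missing))
        stop("regions not present: ", paste(utils::head(missing, 3),
                                            collapse = ", "))
    if (length(subset) < 3L)
        stop("need at least 3 regions to correlate over")
    m <- assay(regionExpr)[, subset, drop = FALSE]
    w <- abs(suppressWarnings(stats::cor(t(m))))
    if (anyNA(w)) {
        nzv <- sum(apply(m, 1L, stats::sd) == 0)
        warning(nzv, " zero-variance gene(s): their edges set to 0")
        w[is.na(w)] <- 0
    }
    w <- pmin(pmax(w, 0), 1)
    diag(w) <- 1
    new("CorrelationNetwork", genes = rownames(m), weights = w,
        regionSubset = as.character(subset), nObs = length(subset))
}

.effectiveSeeds <- function(network, seeds) {
    eff <- intersect(seeds, networkGenes(network))
    dropped <- setdiff(seeds, eff)
    if (length(dropped))
        warning(length(dropped), " seed(s) absent from network dropped: ",
                paste(utils::head(dropped, 3), collapse = ", "))
    if (!length(eff)) stop("no seed gene present in the network")
    eff
}

#' Summed absolute seed correlation for non-seed genes
#'
#' For each queried gene, the sum of its edge weights to all seed genes --
#' the aggregate guilt-by-association signal. Seeds themselves are scored
#' with the leave-one-out procedure [seedCrLoo()] instead.
#'
#' @param network a [CorrelationNetwork-class].
#' @param seeds character vector of seed gene symbols; seeds missing from
#'   the network are dropped with a warning.
#' @param genes genes to score (default: all non-seed genes in the network).
#' @return named numeric vector of summed absolute correlations.
#' @export
seedSums <- function(network, seeds, genes = NULL) {
    eff <- .effectiveSeeds(network, seeds)
    if (is.null(genes)) genes <- setdiff(networkGenes(network), seeds)
    if (any(genes %in% eff))
        stop("seed genes cannot be scored with seedSums; use seedCrLoo()")
    bad <- setdiff(genes, networkGenes(network))
    if (length(bad)) stop("genes not in network: ", paste(bad, collapse = ", "))
    w <- edgeWeights(network)[genes, eff, drop = FALSE]
    rowSums(w)
}

#' @rdname seedSums
#' @param gene a single non-seed gene symbol.
#' @export
seedSum <- function(network, seeds, gene) {
    stopifnot(length(gene) == 1L)
    unname(seedSums(network, seeds, genes = gene))
}

#' Percentile ranks of seed-correlation scores
#'
#' Rank 1 is the largest score. Two orientations are returned:
#' `percentileTop = rank / (N + 1)` is small for strongly seed-correlated
#' genes and feeds the upper-tail normal quantile conversion
#' ([networkZ()]); `cr = 1 - percentileTop` is the tables' orientation
#' (large = strongly seed-co-expressed). Ties get average ranks.
#'
#' @param scores numeric vector of summed absolute correlations.
#' @return data.frame with columns `score`, `percentileTop`, `cr` (row
#'   names taken from `names(scores)`).
#' @export
percentileRanks <- function(scores) {
    if (!length(scores)) stop("no scores to rank")
    r <- rank(-scores, ties.method = "average")
    pTop <- r / (length(scores) + 1)
    data.frame(score = as.vector(scores), percentileTop = pTop,
               cr = 1 - pTop, row.names = names(scores))
}

#' Leave-one-out correlation ranks for seed genes
#'
#' For each seed g, the seed set is reduced to S \ {g}; the summed
#' absolute correlation to the reduced set is computed for g and for every
#' non-seed gene, and g is ranked within that pooled list. Its correlation
#' rank is `cr = 1 - rank / (N + 1)` where N is the pool size, so a seed
#' tightly co-expressed with the remaining seeds approaches cr = 1 and an
#' unrelated seed is uniform on (0, 1). This normalizes each network's
#' correlation distribution onto a common rank scale, making seed-set
#' clustering comparable across networks.
#'
#' @inheritParams seedSums
#' @return `DataFrame` with columns `gene`, `sumAbsCorr` (to the reduced
#'   seed set), `cr`, `isSeed`.
#' @seealso [mrc()] for the median summary.
#' @export
seedCrLoo <- function(network, seeds) {
    eff <- .effectiveSeeds(network, seeds)
    if (length(eff) < 3L)
        stop("leave-one-out CR needs at least 3 seeds in the network")
    w <- edgeWeights(network)
    nonSeeds <- setdiff(networkGenes(network), seeds)
    if (!length(nonSeeds)) stop("network has no non-seed genes to rank against")
    totNS <- rowSums(w[nonSeeds, eff, drop = FALSE])
    cr <- numeric(length(eff))
    sumG <- numeric(length(eff))
    for (i in seq_along(eff)) {
        g <- eff[i]
        reduced <- setdiff(eff, g)
        sumsNS <- totNS - w[nonSeeds, g]
        sG <- sum(w[g, reduced])
        pool <- c(sG, sumsNS)
        rk <- rank(-pool, ties.method = "average")[1L]
        cr[i] <- 1 - rk / (length(pool) + 1)
        sumG[i] <- sG
    }
    DataFrame(gene = eff, sumAbsCorr = sumG, cr = cr, isSeed = TRUE)
}

#' Median ranking by correlation (MRC)
#'
#' The median of the seed genes' leave-one-out correlation ranks in a
#' network: a single number in (0, 1) summarizing how tightly the seed set
#' clusters, comparable across networks because the CRs are rank-uniform
#' under the null. An even count of seeds takes the mean of the two central
#' values.
#'
#' @param crs numeric vector of seed CRs, or the `DataFrame` returned by
#'   [seedCrLoo()].
#' @return the median CR.
#' @export
mrc <- function(crs) {
    if (is(crs, "DataFrame") || is.data.frame(crs)) crs <- crs$cr
    if (!length(crs)) stop("no seed CRs supplied")
    stats::median(crs)
}
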