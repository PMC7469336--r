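#' Per-donor seed correlation ranks
#'
#' Builds one co-expression network per donor (region-level expression
#' from that donor's samples only, restricted to a region subset) and
#' scores every non-seed gene by its correlation rank (CR) to the seed
#' set, yielding a gene x donor matrix of comparable rankings.
#'
#' @inheritParams fitRegionExpression
#' @param seeds character vector of seed gene symbols.
#' @param subset region labels to restrict the networks to (default: all
#'   regions a donor sampled); each donor must retain >= 3 regions.
#' @return numeric matrix, non-seed genes x donors, of CRs.
#' @export
perBrainSeedRanks <- function(se, seeds, granularity = c("low", "mid"),
                              subset = NULL) {
    granularity <- match.arg(granularity)
    brains <- unique(colData(se)$brain_id)
    if (length(brains) < 2L) stop("need >= 2 donors")
    nonSeeds <- setdiff(rownames(se), seeds)
    out <- matrix(NA_real_, length(nonSeeds), length(brains),
                  dimnames = list(nonSeeds, brains))
    for (b in brains) {
        re <- perBrainRegionMeans(se, b, granularity)
        sub <- if (is.null(subset)) regionLabels(re)
               else intersect(subset, regionLabels(re))
        net <- buildNetwork(re, sub)
        sums <- seedSums(net, seeds)
        out[, b] <- percentileRanks(sums)[nonSeeds, "cr"]
    }
    out
}

#' Kendall tau concordance matrix of gene rankings
#'
#' Pairwise Kendall tau-b (tie-corrected) rank correlations between
#' rankings of a common gene universe, e.g. the per-donor CR columns of
#' [perBrainSeedRanks()]. The diagonal is exactly 1.
#'
#' @param rankings numeric matrix, genes x rankings (>= 2 columns), all
#'   columns covering the same gene universe.
#' @return symmetric matrix of tau-b values with unit diagonal.
#' @export
kendallMatrix <- function(rankings) {
    rankings <- as.matrix(rankings)
    if (ncol(rankings) < 2L) stop("need at least 2 rankings")
    if (anyNA(rankings)) stop("rankings must cover the same gene universe")
    tau <- stats::cor(rankings, method = "kendall")
    diag(tau) <- 1
    tau
}

#' Paired comparison of seed CRs between two networks
#'
#' Wilcoxon signed-rank test on paired seed CR vectors (one CR per seed
#' gene per network), two-sided by default, with both medians. The exact
#' distribution is used for n <= 25 (no zero differences or tied absolute
#' differences); larger samples use the normal approximation with
#' continuity correction.
#'
#' @param crA,crB equal-length paired CR vectors.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return list with `medianA`, `medianB`, `statistic`, `p.value`,
#'   `method`.
#' @export
pairedCrTest <- function(crA, crB,
                         alternative = c("two.sided", "less", "greater")) {
    alternative <- match.arg(alternative)
    if (length(crA) != length(crB))
        stop("paired CR vectors must have equal length")
    d <- crA - crB
    if (all(d == 0)) stop("all paired differences are zero")
    exact <- length(d) <= 25L && !any(d == 0) && !anyDuplicated(abs(d[d != 0]))
    wt <- suppressWarnings(
        stats::wilcox.test(crA, crB, paired = TRUE, exact = exact,
                           correct = TRUE, alternative = alternative))
    list(medianA = stats::median(crA), medianB = stats::median(crB),
         statistic = unname(wt$statistic), p.value = wt$p.value,
         method = wt$method)
}
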