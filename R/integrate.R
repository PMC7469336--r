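#' Convert network percentile ranks to Z-scores
#'
#' Upper-tail normal quantile of `percentileTop` (the rank/(N+1) percentile
#' with rank 1 = strongest seed correlation), so top-ranked genes get large
#' positive network Z-scores.
#'
#' @param percentileTop percentile(s) in (0, 1).
#' @return network Z-score(s).
#' @export
networkZ <- function(percentileTop) {
    if (any(!is.finite(percentileTop)) ||
        any(percentileTop <= 0 | percentileTop >= 1))
        stop("percentileTop must lie strictly in (0, 1)")
    stats::qnorm(percentileTop, lower.tail = FALSE)
}

#' Equal-weight Stouffer combination of GWAS and network Z-scores
#'
#' `z_combined = (0.5 z_gwas + 0.5 z_network) / sqrt(0.5^2 + 0.5^2)`,
#' i.e. `(z_gwas + z_network) / sqrt(2)`: the Stouffer weighted-sum
#' meta-analysis statistic with both evidence sources weighted equally, so
#' standard-normal inputs give a standard-normal output.
#'
#' @param zGwas,zNetwork finite Z-score vectors (recycled).
#' @return combined Z-score(s).
#' @export
stoufferCombine <- function(zGwas, zNetwork) {
    if (any(!is.finite(zGwas)) || any(!is.finite(zNetwork)))
        stop("Z-scores must be finite")
    (0.5 * zGwas + 0.5 * zNetwork) / sqrt(0.5^2 + 0.5^2)
}

#' Upper-tail p-value of a combined Z-score
#'
#' @param z finite Z-score(s).
#' @return one-tailed p-value(s), `pnorm(z, lower.tail = FALSE)`.
#' @export
oneTailedP <- function(z) {
    if (any(is.na(z))) stop("z must not be NA")
    stats::pnorm(z, lower.tail = FALSE)
}

#' Benjamini-Hochberg FDR with an explicit test universe size
#'
#' Step-up adjusted q-values `q_(i) = min_{j >= i} p_(j) * m / j`. With the
#' default `m = length(p)` this is `p.adjust(p, "BH")`; a larger `m` scores
#' a reported subset (for example the top rows of a table) against the full
#' universe of tests it was selected from.
#'
#' @param p p-values in (0, 1].
#' @param m universe size, `>= length(p)`.
#' @return q-values in the input order, capped at 1.
#' @export
bhFdr <- function(p, m = length(p)) {
    if (!length(p)) stop("empty p-value vector")
    if (any(!is.finite(p)) || any(p <= 0 | p > 1))
        stop("p-values must lie in (0, 1]")
    if (m < length(p)) stop("universe size m must be >= length(p)")
    if (m == length(p)) return(stats::p.adjust(p, method = "BH"))
    o <- order(p)
    qSorted <- rev(cummin(rev(p[o] * m / seq_along(o))))
    q <- numeric(length(p))
    q[o] <- pmin(qSorted, 1)
    q
}

#' Filter genes by AD-related knockout phenotypes
#'
#' Keeps genes whose model-organism knockout phenotype set intersects the
#' four AD-related codes: defective memory (DM), defective aging (DA),
#' oxidative stress (OS), premature aging (PA). Long phenotype names are
#' accepted and mapped to codes. Genes absent from the table, or present
#' with an empty phenotype set, are dropped (counted in a message).
#'
#' @param genes character vector of candidate gene symbols.
#' @param phenotypeTable data.frame with columns `gene` and `phenotypes`
#'   (comma-separated codes or long names), as from [readPhenotypes()].
#' @return data.frame with columns `gene` and `phenotype` (comma-joined
#'   AD-related codes) for the surviving genes, in input order.
#' @export
phenotypeFilter <- function(genes, phenotypeTable) {
    stopifnot(all(c("gene", "phenotypes") %in% colnames(phenotypeTable)))
    idx <- match(genes, phenotypeTable$gene)
    codes <- lapply(phenotypeTable$phenotypes[idx], .adPhenotypeCodes)
    keep <- !is.na(idx) & lengths(codes) > 0L
    nDropped <- sum(!keep)
    if (nDropped > 0L)
        message(nDropped, " gene(s) without an AD-related knockout phenotype dropped")
    data.frame(gene = genes[keep],
               phenotype = vapply(codes[keep], paste, character(1),
                                  collapse = ","),
               stringsAsFactors = FALSE)
}

.adPhenotypeCodes <- function(x) {
    if (is.na(x) || !nzchar(trimws(x))) return(character(0))
    parts <- trimws(strsplit(x, ",")[[1L]])
    longToCode <- stats::setNames(names(.AD_PHENOTYPES), .AD_PHENOTYPES)
    parts <- ifelse(parts %in% .AD_PHENOTYPES, longToCode[parts], parts)
    intersect(names(.AD_PHENOTYPES), parts)
}

#' Rank novel candidate genes by combined network and GWAS evidence
#'
#' The full prioritization chain for non-seed genes: summed absolute seed
#' correlation in the network, percentile rank and conversion to a network
#' Z-score, hotspot-corrected GWAS Z-score, equal-weight Stouffer
#' combination, knockout-phenotype filter, one-tailed p and BH-FDR over the
#' phenotype-filtered set. Genes lacking a GWAS record are dropped with a
#' message (both evidence sources are required).
#'
#' @param network a [CorrelationNetwork-class] over all genes.
#' @param seeds character vector of seed gene symbols; seed genes are
#'   excluded from the ranking.
#' @param gwas data.frame with `gene`, `p_best`, `n_snps`.
#' @param phenotypeTable data.frame with `gene`, `phenotypes`; `NULL` skips
#'   the filter (all scored genes kept, empty phenotype labels).
#' @return `DataFrame` with columns `gene`, `phenotype`, `zGwas`,
#'   `zNetwork`, `zCombined`, `pOneTailed`, `qFdr`, ordered by `zCombined`
#'   descending (ties broken alphabetically). The metadata records that
#'   GWAS Z-scores come from hotspot-corrected p-values and the FDR
#'   universe size.
#' @export
rankNovelGenes <- function(network, seeds, gwas, phenotypeTable = NULL) {
    sums <- seedSums(network, seeds)
    pr <- percentileRanks(sums)
    zNet <- networkZ(pr$percentileTop)
    names(zNet) <- rownames(pr)

    gScores <- gwasGeneScores(gwas)
    common <- intersect(names(zNet), gScores$gene)
    nNoGwas <- length(zNet) - length(common)
    if (!length(common)) stop("no scored gene has a GWAS record")
    if (nNoGwas > 0L)
        message(nNoGwas, " gene(s) without GWAS records dropped")
    zG <- gScores$z_gwas[match(common, gScores$gene)]
    zN <- unname(zNet[common])

    if (is.null(phenotypeTable)) {
        kept <- data.frame(gene = common, phenotype = "",
                           stringsAsFactors = FALSE)
    } else {
        kept <- phenotypeFilter(common, phenotypeTable)
    }
    sel <- match(kept$gene, common)
    zC <- stoufferCombine(zG[sel], zN[sel])
    p <- oneTailedP(zC)
    q <- bhFdr(p)
    out <- DataFrame(gene = kept$gene, phenotype = kept$phenotype,
                     zGwas = zG[sel], zNetwork = zN[sel], zCombined = zC,
                     pOneTailed = p, qFdr = q)
    out <- out[order(-out$zCombined, out$gene), ]
    rownames(out) <- NULL
    metadata(out) <- list(gwasP = "hotspot_corrected",
                          fdrUniverse = nrow(out))
    out
}
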