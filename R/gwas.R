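#' Reduce SNP-level p-values to per-gene best-SNP records
#'
#' @param snpTable data.frame with columns `gene` and `p` (one row per SNP).
#' @return data.frame with columns `gene`, `p_best` (minimum SNP p within
#'   the gene) and `n_snps` (SNP count), one row per gene.
#' @export
bestSnpReduce <- function(snpTable) {
    stopifnot(all(c("gene", "p") %in% colnames(snpTable)))
    if (!nrow(snpTable)) stop("empty SNP table")
    if (any(!is.finite(snpTable$p)) || any(snpTable$p <= 0 | snpTable$p > 1))
        stop("SNP p-values must lie in (0, 1]")
    g <- factor(snpTable$gene, levels = unique(snpTable$gene))
    data.frame(gene = levels(g),
               p_best = as.vector(tapply(snpTable$p, g, min)),
               n_snps = as.integer(table(g)),
               stringsAsFactors = FALSE)
}

#' Hotspot/LD/gene-size correction of a best-SNP p-value
#'
#' Adjusts a gene's best-SNP p for the number of SNPs it contains with
#' `p_gene = 1 - (1 - p_best)^((N + 1) / 2)`, a closed-form correction that
#' treats `(N + 1) / 2` as the effective number of independent tests -- a
#' conservative count for SNPs correlated through recombination hotspots
#' and linkage disequilibrium. It is the identity at N = 1 and is monotone
#' increasing in both arguments, so `p_gene >= p_best` always.
#'
#' @param pBest best-SNP p-value(s) in (0, 1].
#' @param nSnps SNP count(s) per gene, >= 1 (recycled against `pBest`).
#' @return corrected gene-level p-value(s).
#' @examples
#' hotspotCorrect(0.01, 9)  # 1 - 0.99^5 = 0.0490...
#' @export
hotspotCorrect <- function(pBest, nSnps) {
    if (any(!is.finite(pBest)) || any(pBest <= 0 | pBest > 1))
        stop("pBest must lie in (0, 1]")
    if (any(nSnps < 1)) stop("nSnps must be >= 1")
    # expm1/log1p form keeps precision for tiny p_best
    -expm1(log1p(-pBest) * (nSnps + 1) / 2)
}

#' Convert a p-value to an upper-tail standard-normal Z-score
#'
#' One-tailed convention throughout: small p maps to large positive z.
#' Exact 0 or 1 inputs are clamped to the nearest representable p with a
#' warning.
#'
#' @param p p-value(s) in (0, 1).
#' @return z-score(s), `qnorm(p, lower.tail = FALSE)`.
#' @export
pToZ <- function(p) {
    if (any(!is.finite(p)) || any(p < 0 | p > 1))
        stop("p must lie in [0, 1]")
    if (any(p == 0 | p == 1)) {
        warning("p of exactly 0 or 1 clamped to machine bounds")
        eps <- .Machine$double.xmin
        p <- pmin(pmax(p, eps), 1 - .Machine$double.eps / 2)
    }
    stats::qnorm(p, lower.tail = FALSE)
}

#' Gene-level GWAS association scores
#'
#' Applies the hotspot correction to each gene's best-SNP p and converts
#' the corrected p to an upper-tail Z-score.
#'
#' @param gwas data.frame with columns `gene`, `p_best`, `n_snps` (as
#'   returned by [readGwas()] or [bestSnpReduce()]).
#' @return data.frame with columns `gene`, `p_gene`, `z_gwas`.
#' @export
gwasGeneScores <- function(gwas) {
    .validateGwas(gwas)
    pGene <- hotspotCorrect(gwas$p_best, gwas$n_snps)
    data.frame(gene = gwas$gene, p_gene = pGene, z_gwas = pToZ(pGene),
               stringsAsFactors = FALSE)
}
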