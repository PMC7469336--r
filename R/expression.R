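#' Collapse probe-level rows to gene-level means
#'
#' When several probes interrogate one gene, the gene's expression in each
#' sample is the arithmetic mean of its probes' values. Probes absent from
#' the probe-to-gene map are dropped with a message.
#'
#' @param se `SummarizedExperiment` with probe rows.
#' @param probeMap data.frame with columns `probe`, `gene`.
#' @return `SummarizedExperiment` with one row per gene, same samples and
#'   sample order.
#' @export
collapseProbes <- function(se, probeMap) {
    stopifnot(all(c("probe", "gene") %in% colnames(probeMap)))
    m <- assay(se)
    idx <- match(rownames(m), probeMap$probe)
    unmapped <- sum(is.na(idx))
    if (unmapped > 0L)
        message(unmapped, " unmapped probe(s) dropped")
    keep <- !is.na(idx)
    if (!any(keep)) stop("no probe maps to a gene")
    m <- m[keep, , drop = FALSE]
    gene <- probeMap$gene[idx[keep]]
    sums <- rowsum(m, group = gene, reorder = FALSE)
    means <- sums / as.vector(table(gene)[rownames(sums)])
    SummarizedExperiment(assays = list(expression = means),
                         colData = colData(se))
}

.regionFactor <- function(cd, granularity) {
    switch(granularity, low = cd$region_low, mid = cd$structure_mid)
}

.regionStructureMap <- function(cd, granularity) {
    reg <- .regionFactor(cd, granularity)
    vapply(split(as.character(cd$structure_high), reg),
           function(x) x[1L], character(1))
}

#' Region-level expression via a donor random-intercept mixed model
#'
#' Per gene, fits `expression ~ 0 + region + (1 | brain)` by REML and takes
#' the estimated region cell means (donor effect marginalized out) as the
#' region-level expression, accounting for repeated sampling of both donors
#' and regions. When every donor contributes the same number of samples to
#' every region the generalized-least-squares estimate reduces exactly to
#' the per-region sample mean for any variance components, and that closed
#' form is used directly. Genes whose mixed-model fit fails fall back to
#' plain per-region means (counted in a message).
#'
#' @param se `SummarizedExperiment` from [readExpression()] (or the
#'   synthetic generator) with `brain_id`, `region_low`, `structure_mid`,
#'   `structure_high` in `colData`.
#' @param granularity `"low"` (finest parcellation, default) or `"mid"`.
#' @return A [RegionExpression-class] with `provenance = "mixed_model"`.
#' @export
fitRegionExpression <- function(se, granularity = c("low", "mid")) {
    granularity <- match.arg(granularity)
    cd <- colData(se)
    brain <- factor(cd$brain_id)
    if (nlevels(brain) < 2L)
        stop("mixed-model region expression needs >= 2 donors")
    region <- factor(.regionFactor(cd, granularity))
    m <- assay(se)
    tab <- table(region, brain)
    balanced <- length(unique(as.vector(tab))) == 1L && all(tab > 0L)
    if (balanced) {
        vals <- .regionMeans(m, region)
    } else {
        vals <- .lmerRegionFit(m, region, brain)
    }
    RegionExpression(vals,
                     structureHigh = .regionStructureMap(cd, granularity),
                     provenance = "mixed_model")
}

.regionMeans <- function(m, region) {
    sums <- t(rowsum(t(m), group = region, reorder = TRUE))
    n <- as.vector(table(region)[colnames(sums)])
    sweep(sums, 2L, n, "/")
}

.lmerRegionFit <- function(m, region, brain) {
    levs <- levels(region)
    meansFallback <- .regionMeans(m, region)
    out <- matrix(NA_real_, nrow(m), length(levs),
                  dimnames = list(rownames(m), levs))
    nFail <- 0L
    ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                              check.conv.singular = "ignore")
    for (g in seq_len(nrow(m))) {
        df <- data.frame(y = m[g, ], region = region, brain = brain)
        est <- tryCatch({
            fit <- suppressMessages(suppressWarnings(
                lme4::lmer(y ~ 0 + region + (1 | brain), data = df,
                           REML = TRUE, control = ctrl)))
            fe <- lme4::fixef(fit)
            stats::setNames(unname(fe), sub("^region", "", names(fe)))[levs]
        }, error = function(e) NULL)
        if (is.null(est) || any(!is.finite(est))) {
            nFail <- nFail + 1L
            est <- meansFallback[g, levs]
        }
        out[g, ] <- est
    }
    if (nFail > 0L)
        message(nFail, " gene(s) fell back to plain region means")
    out
}

#' Per-donor region mean expression
#'
#' Region-level expression using the samples of a single donor only: the
#' value of a gene in a region is the mean over that donor's samples in the
#' region. Regions the donor never sampled are dropped.
#'
#' @inheritParams fitRegionExpression
#' @param brainId donor identifier.
#' @return A [RegionExpression-class] with `provenance = "per_brain_mean"`.
#' @export
perBrainRegionMeans <- function(se, brainId, granularity = c("low", "mid")) {
    granularity <- match.arg(granularity)
    cd <- colData(se)
    keep <- cd$brain_id == brainId
    if (!any(keep)) stop("no samples for donor '", brainId, "'")
    sub <- se[, keep]
    cds <- colData(sub)
    region <- factor(.regionFactor(cds, granularity))
    vals <- .regionMeans(assay(sub), droplevels(region))
    RegionExpression(vals,
                     structureHigh = .regionStructureMap(cds, granularity),
                     provenance = "per_brain_mean", brainId = brainId)
}

#' PCA of sample expression vectors for QC
#'
#' Centered (unscaled) principal components of the samples in gene space,
#' joined with the high-level structure and donor labels so batch or
#' structure effects can be inspected on a PC1/PC2 scatter.
#'
#' @param se `SummarizedExperiment` of expression.
#' @param nComponents number of components to return (default 2).
#' @return data.frame with `sample_id`, `PC1..PCk`, `structure_high`,
#'   `brain_id`, plus the proportion of variance per component as the
#'   `"varExplained"` attribute.
#' @export
pcaQC <- function(se, nComponents = 2L) {
    m <- assay(se)
    if (ncol(m) < 3L) stop("PCA QC needs at least 3 samples")
    if (nComponents > min(dim(m)))
        stop("fewer samples/genes than requested components")
    pc <- stats::prcomp(t(m), center = TRUE, scale. = FALSE,
                        rank. = nComponents)
    cd <- colData(se)
    out <- data.frame(sample_id = colnames(m),
                      pc$x[, seq_len(nComponents), drop = FALSE],
                      structure_high = cd$structure_high,
                      brain_id = cd$brain_id,
                      stringsAsFactors = FALSE, row.names = NULL)
    attr(out, "varExplained") <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(nComponents)]
    out
}
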