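#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom methods new validObject is setValidity show callNextMethod
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

.STRUCTURES <- c("cerebrum", "cerebellum", "brain_stem")
.AD_PHENOTYPES <- c(DM = "defective_memory", DA = "defective_aging",
                    OS = "oxidative_stress", PA = "premature_aging")

#' RegionExpression: gene-by-region adjusted expression
#'
#' A \linkS4class{SummarizedExperiment} with one column per brain region at a
#' chosen granularity. The single assay holds region-level expression, either
#' the region fixed effects of a donor random-intercept mixed model
#' (\code{provenance = "mixed_model"}) or plain per-donor region means
#' (\code{provenance = "per_brain_mean"}, with \code{brainId} set). Column
#' data carry at least \code{region} and \code{structure_high}.
#'
#' @slot provenance character, how the region values were derived.
#' @slot brainId character, donor ID for per-donor means (\code{NA} otherwise).
#' @seealso [fitRegionExpression()], [perBrainRegionMeans()], [buildNetwork()]
#' @export
setClass("RegionExpression",
    contains = "SummarizedExperiment",
    representation(provenance = "character", brainId = "character"),
    prototype(provenance = "mixed_model", brainId = NA_character_))

setValidity("RegionExpression", function(object) {
    msg <- character()
    if (length(object@provenance) != 1L ||
        !object@provenance %in% c("mixed_model", "per_brain_mean"))
        msg <- c(msg, "provenance must be 'mixed_model' or 'per_brain_mean'")
    if (length(object@brainId) != 1L)
        msg <- c(msg, "brainId must be a single string (or NA)")
    cd <- colData(object)
    if (!all(c("region", "structure_high") %in% colnames(cd)))
        msg <- c(msg, "colData must contain 'region' and 'structure_high'")
    else if (!all(cd$structure_high %in% .STRUCTURES))
        msg <- c(msg, "structure_high must be one of cerebrum/cerebellum/brain_stem")
    if (length(SummarizedExperiment::assays(object)) >= 1L) {
        v <- assay(object)
        if (!all(is.finite(v)))
            msg <- c(msg, "region expression values must be finite")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a RegionExpression object
#'
#' @param values numeric matrix, genes x regions; column names are region labels.
#' @param structureHigh character vector (one per region) of high-level
#'   structures, or a named vector looked up by region label.
#' @param provenance `"mixed_model"` or `"per_brain_mean"`.
#' @param brainId donor ID when `provenance = "per_brain_mean"`.
#' @return A [RegionExpression-class] object.
#' @export
RegionExpression <- function(values, structureHigh,
                             provenance = c("mixed_model", "per_brain_mean"),
                             brainId = NA_character_) {
    provenance <- match.arg(provenance)
    values <- as.matrix(values)
    if (is.null(colnames(values)))
        stop("'values' must have region labels as column names")
    if (!is.null(names(structureHigh)))
        structureHigh <- unname(structureHigh[colnames(values)])
    if (length(structureHigh) != ncol(values))
        stop("'structureHigh' must give one structure per region column")
    se <- SummarizedExperiment(
        assays = list(expression = values),
        colData = DataFrame(region = colnames(values),
                            structure_high = structureHigh,
                            row.names = colnames(values)))
    new("RegionExpression", se, provenance = provenance,
        brainId = as.character(brainId))
}

#' @describeIn RegionExpression-class derivation of the region values.
#' @param object,x a `RegionExpression` object.
#' @export
provenance <- function(object) object@provenance

#' @describeIn RegionExpression-class donor ID (per-donor means only).
#' @export
brainId <- function(object) object@brainId

#' @describeIn RegionExpression-class region labels (column names).
#' @export
regionLabels <- function(object) colnames(object)

#' @describeIn RegionExpression-class named vector region -> high structure.
#' @export
regionStructures <- function(object) {
    cd <- colData(object)
    stats::setNames(as.character(cd$structure_high), cd$region)
}

setMethod("show", "RegionExpression", function(object) {
    callNextMethod()
    cat("provenance:", object@provenance)
    if (!is.na(object@brainId)) cat("  brainId:", object@brainId)
    cat("\n")
})

#' CorrelationNetwork: absolute-Pearson gene co-expression network
#'
#' A symmetric gene-by-gene matrix of absolute Pearson correlation
#' coefficients computed across the columns (regions) of a
#' [RegionExpression-class] restricted to a stated region subset. The
#' diagonal is stored as 1 by convention and is excluded from all scoring.
#'
#' @slot genes character, node labels.
#' @slot weights numeric matrix in `[0, 1]`, symmetric.
#' @slot regionSubset character, regions the correlations were computed over.
#' @slot nObs integer, number of observations (regions) per correlation.
#' @seealso [buildNetwork()], [seedSums()], [seedCrLoo()]
#' @export
setClass("CorrelationNetwork",
    representation(genes = "character", weights = "matrix",
                   regionSubset = "character", nObs = "integer"))

setValidity("CorrelationNetwork", function(object) {
    msg <- character()
    w <- object@weights
    g <- object@genes
    if (nrow(w) != length(g) || ncol(w) != length(g))
        msg <- c(msg, "weights must be a |genes| x |genes| matrix")
    if (anyDuplicated(g))
        msg <- c(msg, "gene labels must be unique")
    if (length(object@nObs) != 1L || is.na(object@nObs) || object@nObs < 3L)
        msg <- c(msg, "nObs must be a single integer >= 3")
    if (length(msg) == 0L) {
        if (!isTRUE(all.equal(w, t(w), tolerance = 1e-10,
                              check.attributes = FALSE)))
            msg <- c(msg, "weights must be symmetric")
        if (any(!is.finite(w)) || min(w) < -1e-10 || max(w) > 1 + 1e-10)
            msg <- c(msg, "weights must lie in [0, 1]")
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn CorrelationNetwork-class gene (node) labels.
#' @param object,x a `CorrelationNetwork`.
#' @export
networkGenes <- function(object) object@genes

#' @describeIn CorrelationNetwork-class symmetric `[0,1]` weight matrix.
#' @export
edgeWeights <- function(object) object@weights

#' @describeIn CorrelationNetwork-class regions the network was built over.
#' @export
regionSubset <- function(object) object@regionSubset

#' @describeIn CorrelationNetwork-class observations per correlation.
#' @export
nObservations <- function(object) object@nObs

setMethod("show", "CorrelationNetwork", function(object) {
    cat("CorrelationNetwork with", length(object@genes), "genes over",
        length(object@regionSubset), "regions (n =", object@nObs, "obs)\n")
    w <- object@weights
    off <- w[upper.tri(w)]
    if (length(off))
        cat(sprintf("  |r| edge weights: median %.3f, max %.3f\n",
                    stats::median(off), max(off)))
})
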