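#' Read an expression matrix with sample annotations
#'
#' Reads a genes-x-samples TSV (header row of sample IDs, first column of
#' gene/probe IDs) plus an annotation TSV with columns `sample_id`,
#' `brain_id`, `structure_high`, `structure_mid`, `region_low`, and returns a
#' validated \linkS4class{SummarizedExperiment}. Every expression column must
#' be annotated; samples are matched case-sensitively. Missing or non-numeric
#' expression values are rejected rather than imputed.
#'
#' @param path expression TSV path.
#' @param annotationPath sample annotation TSV path.
#' @return A `SummarizedExperiment` with one `expression` assay and the four
#'   annotation fields in `colData`.
#' @examples
#' ex <- system.file("extdata", package = "SeedCoNet")
#' @export
readExpression <- function(path, annotationPath) {
    raw <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    if (ncol(raw) < 2L) stop("expression TSV needs an ID column plus samples")
    ids <- as.character(raw[[1L]])
    if (anyDuplicated(ids))
        stop("duplicate row identifiers in expression matrix: ",
             paste(unique(ids[duplicated(ids)])[1:3], collapse = ", "))
    m <- as.matrix(raw[, -1L, drop = FALSE])
    if (!is.numeric(m)) stop("non-numeric cells in expression matrix")
    if (any(!is.finite(m)))
        stop("missing or non-finite expression values are not supported")
    rownames(m) <- ids
    if (anyDuplicated(colnames(m))) stop("duplicate sample IDs in header")
    ann <- .readAnnotations(annotationPath)
    missing <- setdiff(colnames(m), ann$sample_id)
    if (length(missing))
        stop("samples without annotations: ",
             paste(utils::head(missing, 3), collapse = ", "))
    ann <- ann[match(colnames(m), ann$sample_id), , drop = FALSE]
    SummarizedExperiment(
        assays = list(expression = m),
        colData = DataFrame(ann, row.names = ann$sample_id))
}

.readAnnotations <- function(path) {
    ann <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("sample_id", "brain_id", "structure_high", "structure_mid",
              "region_low")
    if (!all(need %in% colnames(ann)))
        stop("annotation TSV must contain columns: ",
             paste(need, collapse = ", "))
    if (anyDuplicated(ann$sample_id)) stop("duplicate sample_id in annotations")
    bad <- setdiff(unique(ann$structure_high), .STRUCTURES)
    if (length(bad))
        stop("unknown structure_high level(s): ", paste(bad, collapse = ", "))
    # the three-tier hierarchy must nest: a fine region belongs to exactly one
    # mid-level structure, and a mid-level structure to one high-level one
    if (any(tapply(ann$structure_mid, ann$region_low,
                   function(x) length(unique(x))) > 1L))
        stop("region_low labels must nest uniquely within structure_mid")
    if (any(tapply(ann$structure_high, ann$structure_mid,
                   function(x) length(unique(x))) > 1L))
        stop("structure_mid labels must nest uniquely within structure_high")
    ann[, need]
}

#' Write an expression matrix (or RegionExpression assay) as TSV
#'
#' Values are written with 15 significant digits so that a write/read
#' round trip preserves them to at least 12 significant digits.
#'
#' @param x matrix, `SummarizedExperiment` or [RegionExpression-class].
#' @param path output TSV path.
#' @export
writeExpression <- function(x, path) {
    if (is(x, "SummarizedExperiment")) x <- assay(x)
    df <- data.frame(id = rownames(x),
                     signif(x, 15),
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read gene-level or SNP-level GWAS association results
#'
#' Accepts either a gene-level TSV with columns `gene`, `p_best`, `n_snps`,
#' or a SNP-level TSV with columns `gene` and `p` (one row per SNP), which is
#' reduced with [bestSnpReduce()]. All p-values must lie in (0, 1] and SNP
#' counts must be positive.
#'
#' @param path TSV path.
#' @return data.frame with columns `gene`, `p_best`, `n_snps`.
#' @export
readGwas <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (all(c("gene", "p_best", "n_snps") %in% colnames(df))) {
        out <- df[, c("gene", "p_best", "n_snps")]
    } else if (all(c("gene", "p") %in% colnames(df))) {
        out <- bestSnpReduce(df)
    } else {
        stop("GWAS TSV needs columns (gene, p_best, n_snps) or (gene, p)")
    }
    .validateGwas(out)
    out
}

.validateGwas <- function(df) {
    if (any(!is.finite(df$p_best)) || any(df$p_best <= 0 | df$p_best > 1))
        stop("p_best must lie in (0, 1]")
    if (any(df$n_snps < 1L)) stop("n_snps must be >= 1")
    if (anyDuplicated(df$gene)) stop("duplicate gene in GWAS table")
    invisible(df)
}

#' Read a seed gene list (one symbol per line)
#'
#' @param path plain-text path, one gene symbol per line.
#' @return character vector of unique symbols, order preserved.
#' @export
readSeedSet <- function(path) {
    genes <- readLines(path)
    genes <- genes[nzchar(trimws(genes))]
    genes <- trimws(genes)
    if (!length(genes)) stop("empty seed gene list")
    if (anyDuplicated(genes))
        stop("duplicate seed symbols: ",
             paste(unique(genes[duplicated(genes)]), collapse = ", "))
    genes
}

#' Read a gene-to-knockout-phenotype table
#'
#' TSV with columns `gene`, `phenotypes` (comma-separated codes or long
#' names; may be empty) and optionally `ortholog_id`.
#'
#' @param path TSV path.
#' @return data.frame with columns `gene`, `phenotypes`, `ortholog_id`.
#' @export
readPhenotypes <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
    if (!all(c("gene", "phenotypes") %in% colnames(df)))
        stop("phenotype TSV needs columns 'gene' and 'phenotypes'")
    if (!"ortholog_id" %in% colnames(df)) df$ortholog_id <- NA_character_
    df$phenotypes[is.na(df$phenotypes)] <- ""
    df[, c("gene", "phenotypes", "ortholog_id")]
}

#' Write a ranked-result table as TSV
#'
#' @param results a data.frame or `DataFrame` of ranked genes.
#' @param path output TSV path.
#' @export
writeResults <- function(results, path) {
    utils::write.table(as.data.frame(results), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}
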