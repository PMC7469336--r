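#' Curated reference tables for the 52-gene AD seed set
#'
#' Small reference tables shipped with the package: the 52 established
#' ("reproducible") Alzheimer-disease seed genes, their correlation ranks
#' (CRs) across the three high-level brain structures and across the
#' early-/late-stage cerebral region networks, and the top-ranked novel
#' candidate table combining GWAS and network Z-scores with knockout
#' phenotypes. They serve as worked-example inputs and as regression
#' anchors for the ranking arithmetic.
#'
#' @return `radGenes()`: character vector of the 52 seed symbols.
#' @name fixtures
NULL

.extdata <- function(file) {
    path <- system.file("extdata", file, package = "SeedCoNet",
                        mustWork = TRUE)
    utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname fixtures
#' @export
radGenes <- function() {
    readSeedSet(system.file("extdata", "rad_genes.txt",
                            package = "SeedCoNet", mustWork = TRUE))
}

#' @rdname fixtures
#' @return `radStructureRanks()`: data.frame of seed CRs with columns
#'   `gene`, `brain_stem`, `cerebellum`, `cerebrum` (52 rows).
#' @export
radStructureRanks <- function() .extdata("rad_structure_cr.tsv")

#' @rdname fixtures
#' @return `radStageRanks()`: data.frame of seed CRs with columns `gene`,
#'   `early`, `late` (52 rows).
#' @export
radStageRanks <- function() .extdata("rad_stage_cr.tsv")

#' @rdname fixtures
#' @return `combinedRankingTable()`: data.frame of the 36 top-ranked
#'   phenotype-filtered candidates with columns `gene`, `phenotype`,
#'   `z_gwas`, `z_network`, `z_combined`, `p_unadjusted`, `q_fdr`.
#' @export
combinedRankingTable <- function() .extdata("combined_ranking.tsv")
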