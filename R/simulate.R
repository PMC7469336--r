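#' Simulation configuration for the synthetic study generator
#'
#' Defaults mirror the scale of a multi-donor brain-wide expression atlas:
#' 6 donors, a cerebrum split into 79 early-affected and 37 late-affected
#' regions (the Braak-stage subsets used for the stage-restricted
#' networks), plus cerebellum and brain stem, with a handful of samples
#' per region per donor. Seed (and planted signal) genes load on one
#' latent factor per region within each structure subset, producing
#' structure-graded seed co-expression; all other genes are null.
#'
#' @param nGenes total number of genes (seeds + signal + null).
#' @param nSeed number of seed genes (default 52).
#' @param nBrains number of donors (default 6).
#' @param regions named integer vector: regions per structure subset
#'   (`cerebrum_early`, `cerebrum_late`, `cerebellum`, `brain_stem`).
#' @param samplesPerRegionPerBrain samples drawn from each region in each
#'   donor (balanced design).
#' @param loadings named numeric vector in `[0, 1]`: latent-factor loading
#'   of seed/signal genes per structure subset.
#' @param sigmaRegion SD of per-gene region effects (expression units).
#' @param sigmaBrain SD of per-gene donor random intercepts.
#' @param sigmaNoise residual SD per sample.
#' @param nSignalGenes non-seed genes given both an elevated GWAS Z and
#'   the seed-module loading (the planted novel genes).
#' @param gwasEffect mean of the signal genes' GWAS Z-scores.
#' @param fracAdPhenotype fraction of non-seed genes carrying at least one
#'   AD-related knockout phenotype (signal genes always do).
#' @param rngSeed integer seed; all randomness flows from it.
#' @return a validated `SimConfig` list.
#' @export
simConfig <- function(nGenes = 500L, nSeed = 52L, nBrains = 6L,
                      regions = c(cerebrum_early = 79L, cerebrum_late = 37L,
                                  cerebellum = 15L, brain_stem = 25L),
                      samplesPerRegionPerBrain = 2L,
                      loadings = c(cerebrum_early = 0.45, cerebrum_late = 0.60,
                                   cerebellum = 0.25, brain_stem = 0.35),
                      sigmaRegion = 1, sigmaBrain = 0.5, sigmaNoise = 0.1,
                      nSignalGenes = 10L, gwasEffect = 3,
                      fracAdPhenotype = 0.654, rngSeed = 1L) {
    cfg <- list(nGenes = as.integer(nGenes), nSeed = as.integer(nSeed),
                nBrains = as.integer(nBrains), regions = regions,
                samplesPerRegionPerBrain = as.integer(samplesPerRegionPerBrain),
                loadings = loadings, sigmaRegion = sigmaRegion,
                sigmaBrain = sigmaBrain, sigmaNoise = sigmaNoise,
                nSignalGenes = as.integer(nSignalGenes),
                gwasEffect = gwasEffect,
                fracAdPhenotype = fracAdPhenotype,
                rngSeed = as.integer(rngSeed))
    keys <- c("cerebrum_early", "cerebrum_late", "cerebellum", "brain_stem")
    if (!all(keys %in% names(cfg$regions)))
        stop("regions must name: ", paste(keys, collapse = ", "))
    if (!all(keys %in% names(cfg$loadings)))
        stop("loadings must name: ", paste(keys, collapse = ", "))
    if (any(cfg$loadings < 0 | cfg$loadings > 1))
        stop("loadings must lie in [0, 1]")
    if (cfg$nSeed + cfg$nSignalGenes >= cfg$nGenes)
        stop("nGenes must exceed nSeed + nSignalGenes")
    if (cfg$nSeed < 3L) stop("need at least 3 seed genes")
    if (cfg$nBrains < 1L) stop("need at least 1 donor")
    if (cfg$fracAdPhenotype < 0 || cfg$fracAdPhenotype > 1)
        stop("fracAdPhenotype must lie in [0, 1]")
    if (any(c(cfg$sigmaRegion, cfg$sigmaBrain, cfg$sigmaNoise) < 0))
        stop("sigmas must be non-negative")
    class(cfg) <- "SimConfig"
    cfg
}

.withSeed <- function(seed, expr) {
    hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (hadSeed) old <- get(".Random.seed", envir = globalenv())
    on.exit(if (hadSeed) assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv(),
                            inherits = FALSE))
                rm(".Random.seed", envir = globalenv()))
    set.seed(seed)
    expr
}

.simRegionTable <- function(regions) {
    key2high <- c(cerebrum_early = "cerebrum", cerebrum_late = "cerebrum",
                  cerebellum = "cerebellum", brain_stem = "brain_stem")
    key2prefix <- c(cerebrum_early = "CXE", cerebrum_late = "CXL",
                    cerebellum = "CB", brain_stem = "BS")
    mids <- list(cerebrum_early = c("FL", "TL", "OL", "PL"),
                 cerebrum_late = c("Ins", "PHG", "Amg"),
                 cerebellum = c("CbCx", "CbN"),
                 brain_stem = c("MES", "MY", "Bpons"))
    do.call(rbind, lapply(names(regions), function(k) {
        n <- regions[[k]]
        midPool <- paste0(mids[[k]], if (k %in% c("cerebrum_early",
                                                  "cerebrum_late")) "" else "")
        data.frame(region = sprintf("%s%02d", key2prefix[[k]], seq_len(n)),
                   subset_key = k,
                   structure_high = key2high[[k]],
                   structure_mid = rep_len(midPool, n),
                   stringsAsFactors = FALSE)
    }))
}

#' Generate a synthetic multi-donor brain expression study
#'
#' Expression of gene g in sample s is
#' `mu_g + beta_{g,region(s)} + lambda_{g,structure} * F_region +
#' u_{g,brain(s)} + eps`, with per-gene iid region effects `beta`
#' (SD `sigmaRegion`), one standard-normal latent factor value `F` per
#' region shared by all loaded genes, donor random intercepts `u`
#' (SD `sigmaBrain`) and residual noise (SD `sigmaNoise`). `lambda` equals
#' the configured structure-subset loading for seed and signal genes and 0
#' otherwise, so seed co-expression strength is graded by structure.
#' Matched gene-level GWAS records (Z ~ N(0,1) null, N(gwasEffect, 1) for
#' signal genes; reported as upper-tail p with `n_snps = 1`) and a
#' knockout-phenotype table (a configured fraction of non-seed genes carry
#' AD-related codes, always including the signal genes) are emitted
#' alongside the ground truth.
#'
#' @param config a [simConfig()] object.
#' @return list with elements `expression` (a `SummarizedExperiment` with
#'   full sample annotations), `gwas`, `phenotypes` (data.frames in the
#'   dialects [readGwas()]/[readPhenotypes()] read), and `truth` (seed and
#'   signal gene IDs, loadings, realized region effects, early/late region
#'   labels, true GWAS Z, config).
#' @export
simulateStudy <- function(config = simConfig()) {
    stopifnot(inherits(config, "SimConfig"))
    .withSeed(config$rngSeed, {
        regTab <- .simRegionTable(config$regions)
        nR <- nrow(regTab)
        nG <- config$nGenes
        seedGenes <- sprintf("seed%03d", seq_len(config$nSeed))
        signalGenes <- if (config$nSignalGenes > 0L)
            sprintf("sig%03d", seq_len(config$nSignalGenes)) else character(0)
        nullGenes <- sprintf("g%05d",
            seq_len(nG - config$nSeed - config$nSignalGenes))
        genes <- c(seedGenes, signalGenes, nullGenes)

        mu <- stats::rnorm(nG, mean = 7, sd = 1)
        beta <- matrix(stats::rnorm(nG * nR, sd = config$sigmaRegion), nG, nR)
        Freg <- stats::rnorm(nR)
        lambdaKey <- config$loadings[regTab$subset_key]
        loaded <- genes %in% c(seedGenes, signalGenes)
        lambda <- outer(as.numeric(loaded), as.numeric(lambdaKey))
        regionEffects <- mu + beta + lambda * rep(Freg, each = nG)
        dimnames(regionEffects) <- list(genes, regTab$region)

        brains <- sprintf("B%02d", seq_len(config$nBrains))
        reps <- config$samplesPerRegionPerBrain
        ann <- data.frame(
            sample_id = NA_character_,
            brain_id = rep(brains, each = nR * reps),
            structure_high = rep(rep(regTab$structure_high, each = reps),
                                 times = config$nBrains),
            structure_mid = rep(rep(regTab$structure_mid, each = reps),
                                times = config$nBrains),
            region_low = rep(rep(regTab$region, each = reps),
                             times = config$nBrains),
            stringsAsFactors = FALSE)
        ann$sample_id <- sprintf("S%05d", seq_len(nrow(ann)))
        u <- matrix(stats::rnorm(nG * config$nBrains, sd = config$sigmaBrain),
                    nG, config$nBrains, dimnames = list(genes, brains))
        expr <- regionEffects[, ann$region_low, drop = FALSE] +
            u[, ann$brain_id, drop = FALSE] +
            matrix(stats::rnorm(nG * nrow(ann), sd = config$sigmaNoise),
                   nG, nrow(ann))
        colnames(expr) <- ann$sample_id
        se <- SummarizedExperiment(
            assays = list(expression = expr),
            colData = DataFrame(ann, row.names = ann$sample_id))

        zTrue <- stats::rnorm(nG)
        zTrue[genes %in% signalGenes] <-
            stats::rnorm(length(signalGenes), mean = config$gwasEffect)
        gwas <- data.frame(gene = genes,
                           p_best = stats::pnorm(zTrue, lower.tail = FALSE),
                           n_snps = 1L, stringsAsFactors = FALSE)

        nonSeed <- c(signalGenes, nullGenes)
        nCarrier <- max(length(signalGenes),
                        round(config$fracAdPhenotype * length(nonSeed)))
        extra <- sample(nullGenes, nCarrier - length(signalGenes))
        carriers <- c(signalGenes, extra)
        phen <- vapply(seq_along(carriers), function(i) {
            paste(sample(names(.AD_PHENOTYPES), sample(1:2, 1L)),
                  collapse = ",")
        }, character(1))
        phenotypes <- data.frame(
            gene = nonSeed,
            phenotypes = ifelse(nonSeed %in% carriers,
                                phen[match(nonSeed, carriers)], ""),
            ortholog_id = sprintf("FBgn%07d", seq_along(nonSeed)),
            stringsAsFactors = FALSE)

        truth <- list(seedGenes = seedGenes, signalGenes = signalGenes,
                      loadings = config$loadings,
                      regionEffects = regionEffects,
                      regionTable = regTab,
                      earlyRegions = regTab$region[
                          regTab$subset_key == "cerebrum_early"],
                      lateRegions = regTab$region[
                          regTab$subset_key == "cerebrum_late"],
                      latentFactor = stats::setNames(Freg, regTab$region),
                      zTrue = stats::setNames(zTrue, genes),
                      config = config)
        list(expression = se, gwas = gwas, phenotypes = phenotypes,
             truth = truth)
    })
}

#' Simulate null GWAS SNP p-values with within-gene LD
#'
#' Draws per-gene SNP z-scores from an exchangeable multivariate normal
#' (`z_i = sqrt(rho) u + sqrt(1-rho) e_i`) under the null and reports
#' two-sided p-values, one row per SNP. With `rho > 0` the SNPs of a gene
#' are LD-correlated, the regime the hotspot correction's effective test
#' count `(N+1)/2` is conservative for.
#'
#' @param nGenes number of genes.
#' @param snpsPerGene SNPs per gene (scalar or length-`nGenes` vector).
#' @param rho exchangeable within-gene correlation of SNP z-scores.
#' @param rngSeed integer seed.
#' @return data.frame with columns `gene`, `snp`, `p`.
#' @export
simulateNullSnps <- function(nGenes, snpsPerGene, rho = 0.8, rngSeed = 1L) {
    stopifnot(rho >= 0, rho < 1, all(snpsPerGene >= 1))
    n <- rep_len(as.integer(snpsPerGene), nGenes)
    .withSeed(rngSeed, {
        gene <- rep(sprintf("g%05d", seq_len(nGenes)), times = n)
        u <- rep(stats::rnorm(nGenes), times = n)
        z <- sqrt(rho) * u + sqrt(1 - rho) * stats::rnorm(sum(n))
        data.frame(gene = gene,
                   snp = sprintf("rs%07d", seq_len(sum(n))),
                   p = 2 * stats::pnorm(-abs(z)),
                   stringsAsFactors = FALSE)
    })
}

#' Write the sample annotations of an expression object as TSV
#'
#' @param se `SummarizedExperiment` with the four annotation fields.
#' @param path output TSV path.
#' @export
writeAnnotations <- function(se, path) {
    cd <- as.data.frame(colData(se))
    need <- c("sample_id", "brain_id", "structure_high", "structure_mid",
              "region_low")
    utils::write.table(cd[, need], path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
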