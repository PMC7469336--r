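simpleSE <- function(m, ann) {
    SummarizedExperiment(assays = list(expression = m),
                         colData = DataFrame(ann, row.names = ann$sample_id))
}

library(SummarizedExperiment)

test_that("collapseProbes averages probes per gene and keeps sample order", {
    m <- rbind(p1 = c(1, 5), p2 = c(3, 7), p3 = c(10, 20))
    colnames(m) <- c("s1", "s2")
    ann <- data.frame(sample_id = c("s1", "s2"), brain_id = "B1",
                      structure_high = "cerebrum", structure_mid = "FL",
                      region_low = "r1")
    se <- simpleSE(m, ann)
    pm <- data.frame(probe = c("p1", "p2", "p3"),
                     gene = c("gA", "gA", "gB"))
    out <- collapseProbes(se, pm)
    expect_identical(colnames(out), c("s1", "s2"))
    expect_equal(assay(out)["gA", ], c(s1 = 2, s2 = 6))
    expect_equal(assay(out)["gB", ], c(s1 = 10, s2 = 20))

    # single-probe gene passes through unchanged; unmapped probes dropped
    pm2 <- data.frame(probe = "p3", gene = "gB")
    expect_message(out2 <- collapseProbes(se, pm2), "2 unmapped")
    expect_equal(assay(out2)["gB", ], m["p3", ])
    expect_error(collapseProbes(se, data.frame(probe = "x", gene = "y")),
                 "no probe maps")
})

test_that("collapseProbes equals an independent per-gene mean oracle", {
    set.seed(11)
    m <- matrix(rnorm(50 * 10), 50, 10,
                dimnames = list(sprintf("p%02d", 1:50),
                                sprintf("s%02d", 1:10)))
    ann <- data.frame(sample_id = colnames(m), brain_id = "B1",
                      structure_high = "cerebrum", structure_mid = "FL",
                      region_low = "r1")
    pm <- data.frame(probe = rownames(m),
                     gene = sample(sprintf("g%02d", 1:10), 50, replace = TRUE))
    out <- collapseProbes(simpleSE(m, ann), pm)
    for (g in rownames(out)) {
        probes <- pm$probe[pm$gene == g]
        expected <- colMeans(m[probes, , drop = FALSE])
        expect_equal(assay(out)[g, ], expected)
    }
})

regionAnn <- function(regions, brains, reps = 1L, high = "cerebrum") {
    ann <- expand.grid(rep = seq_len(reps), region_low = regions,
                       brain_id = brains, stringsAsFactors = FALSE)
    data.frame(sample_id = sprintf("s%03d", seq_len(nrow(ann))),
               brain_id = ann$brain_id,
               structure_high = rep_len(high, nrow(ann)),
               structure_mid = paste0("m_", ann$region_low),
               region_low = ann$region_low,
               stringsAsFactors = FALSE)
}

test_that("region fit collapses to per-region means with zero donor variance", {
    ann <- regionAnn(c("r1", "r2", "r3"), c("B1", "B2"), reps = 2L)
    set.seed(1)
    regEff <- c(r1 = 1, r2 = 3, r3 = -2)
    m <- matrix(regEff[ann$region_low] + rnorm(nrow(ann), sd = 0.01),
                1, nrow(ann), dimnames = list("g1", ann$sample_id))
    re <- fitRegionExpression(simpleSE(m, ann))
    byRegion <- tapply(m["g1", ], ann$region_low, mean)
    expect_equal(assay(re)["g1", names(byRegion)], c(byRegion),
                 ignore_attr = TRUE)
})

test_that("region contrast is exact for additive noise-free construction", {
    # one gene, two regions, two donors: y = beta_region + u_brain
    ann <- regionAnn(c("r1", "r2"), c("B1", "B2"))
    y <- c(1 + 0.5, 4 + 0.5, 1 - 0.5, 4 - 0.5)  # order: r1B1 r2B1 r1B2 r2B2
    m <- matrix(y, 1, 4, dimnames = list("g1", ann$sample_id))
    re <- fitRegionExpression(simpleSE(m, ann))
    expect_equal(assay(re)["g1", "r2"] - assay(re)["g1", "r1"], 3,
                 tolerance = 1e-6)
})

test_that("balanced-design closed form agrees with the per-gene lmer fit", {
    set.seed(21)
    ann <- regionAnn(c("r1", "r2", "r3", "r4"), c("B1", "B2", "B3"), reps = 2L)
    n <- nrow(ann)
    m <- matrix(rnorm(5 * n), 5, n,
                dimnames = list(paste0("g", 1:5), ann$sample_id))
    u <- matrix(rnorm(5 * 3, sd = 2), 5, 3,
                dimnames = list(NULL, c("B1", "B2", "B3")))
    m <- m + u[, ann$brain_id]
    se <- simpleSE(m, ann)
    fast <- assay(fitRegionExpression(se))  # balanced -> closed form
    region <- factor(ann$region_low); brain <- factor(ann$brain_id)
    for (g in rownames(m)) {
        fit <- suppressMessages(lme4::lmer(
            m[g, ] ~ 0 + region + (1 | brain), REML = TRUE))
        fe <- lme4::fixef(fit)
        expect_equal(unname(fast[g, levels(region)]), unname(fe),
                     tolerance = 1e-6)
    }
})

test_that("mixed-model fit recovers planted region effects on unbalanced data", {
    cfg <- smallConfig(nGenes = 20L, nSeed = 4L, nBrains = 6L,
                       samplesPerRegionPerBrain = 2L, rngSeed = 5L)
    sim <- simulateStudy(cfg)
    se <- sim$expression
    set.seed(9)
    keep <- sort(sample(ncol(se), floor(0.9 * ncol(se))))  # unbalance it
    seU <- se[, keep]
    re <- fitRegionExpression(seU)
    truth <- sim$truth$regionEffects[rownames(re), regionLabels(re)]
    cors <- vapply(seq_len(nrow(re)),
                   function(i) cor(assay(re)[i, ], truth[i, ]), numeric(1))
    expect_gt(min(cors), 0.99)
    expect_error(fitRegionExpression(se[, colData(se)$brain_id == "B01"]),
                 ">= 2 donors")
})

test_that("per-donor region means equal a group-by mean oracle", {
    ann <- regionAnn(c("r1", "r2"), c("B1", "B2"), reps = 2L)
    set.seed(3)
    m <- matrix(rnorm(3 * nrow(ann)), 3, nrow(ann),
                dimnames = list(paste0("g", 1:3), ann$sample_id))
    re <- perBrainRegionMeans(simpleSE(m, ann), "B2")
    expect_identical(provenance(re), "per_brain_mean")
    expect_identical(brainId(re), "B2")
    sel <- ann$brain_id == "B2"
    for (g in rownames(m)) {
        oracle <- tapply(m[g, sel], ann$region_low[sel], mean)
        expect_equal(assay(re)[g, names(oracle)], c(oracle),
                     ignore_attr = TRUE)
    }
    # two samples valued 2 and 4 in one region average to 3
    ann2 <- regionAnn("r1", "B1", reps = 2L)
    m2 <- matrix(c(2, 4), 1, 2, dimnames = list("g", ann2$sample_id))
    expect_equal(unname(assay(perBrainRegionMeans(simpleSE(m2, ann2),
                                                  "B1"))[1, 1]), 3)
    expect_error(perBrainRegionMeans(simpleSE(m, ann), "B9"), "no samples")
})

test_that("per-donor means match the mixed-model fit restricted to one donor", {
    sim <- simulateStudy(smallConfig(rngSeed = 8L))
    re1 <- perBrainRegionMeans(sim$expression, "B01")
    sub <- sim$expression[, colData(sim$expression)$brain_id == "B01"]
    oracle <- tapply(assay(sub)[1, ], colData(sub)$region_low, mean)
    expect_equal(assay(re1)[1, names(oracle)], c(oracle),
                 ignore_attr = TRUE)
})

test_that("PCA QC separates constructed clusters and is rotation-invariant", {
    set.seed(13)
    n <- 20
    cloud <- cbind(matrix(rnorm(50 * n), 50, n),
                   matrix(rnorm(50 * n, mean = 4), 50, n))
    colnames(cloud) <- sprintf("s%02d", seq_len(2 * n))
    rownames(cloud) <- sprintf("g%02d", 1:50)
    ann <- data.frame(sample_id = colnames(cloud), brain_id = "B1",
                      structure_high = rep(c("cerebrum", "cerebellum"),
                                           each = n),
                      structure_mid = rep(c("FL", "CbCx"), each = n),
                      region_low = rep(c("r1", "r2"), each = n))
    se <- simpleSE(cloud, ann)
    qc <- pcaQC(se)
    labels <- rep(1:2, each = n)
    sil <- cluster::silhouette(labels, dist(qc$PC1))
    expect_gt(mean(sil[, "sil_width"]), 0.5)

    # duplicated samples land on identical coordinates
    dup <- cloud[, c(1, 1, 2:10)]
    colnames(dup) <- sprintf("d%02d", 1:11)
    annD <- ann[c(1, 1, 2:10), ]; annD$sample_id <- colnames(dup)
    qcD <- pcaQC(simpleSE(dup, annD))
    expect_equal(qcD[1, c("PC1", "PC2")], qcD[2, c("PC1", "PC2")],
                 ignore_attr = TRUE)

    # orthogonal rotation of gene space leaves scores unchanged up to sign
    q <- qr.Q(qr(matrix(rnorm(50 * 50), 50)))
    qcR <- pcaQC(simpleSE(q %*% cloud, ann))
    expect_equal(abs(qcR$PC1), abs(qc$PC1), tolerance = 1e-8)

    expect_error(pcaQC(se[, 1:2]), "at least 3 samples")
})
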