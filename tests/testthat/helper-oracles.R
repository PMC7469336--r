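# Independent brute-force oracles, deliberately written from the textbook
# definitions rather than via the package (or the stats shortcuts) they check.

brutePearson <- function(x, y) {
    n <- length(x)
    mx <- sum(x) / n; my <- sum(y) / n
    num <- sum((x - mx) * (y - my))
    den <- sqrt(sum((x - mx)^2) * sum((y - my)^2))
    num / den
}

bruteAbsCorMatrix <- function(m) {
    n <- nrow(m)
    w <- matrix(1, n, n, dimnames = list(rownames(m), rownames(m)))
    for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
        w[i, j] <- abs(brutePearson(m[i, ], m[j, ]))
    w
}

bruteSeedSum <- function(w, seeds, gene) {
    s <- 0
    for (sd in seeds) if (sd != gene) s <- s + w[gene, sd]
    s
}

brutePercentiles <- function(scores) {
    n <- length(scores)
    pt <- numeric(n)
    for (i in seq_len(n)) {
        higher <- sum(scores > scores[i])
        ties <- sum(scores == scores[i])
        pt[i] <- (higher + (ties + 1) / 2) / (n + 1)  # average rank
    }
    pt
}

# tau-b from explicit concordant/discordant/tie pair counts
bruteTauB <- function(a, b) {
    n <- length(a); C <- 0; D <- 0; Ta <- 0; Tb <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        da <- a[i] - a[j]; db <- b[i] - b[j]
        if (da == 0 && db == 0) next
        else if (da == 0) Ta <- Ta + 1
        else if (db == 0) Tb <- Tb + 1
        else if (sign(da) == sign(db)) C <- C + 1
        else D <- D + 1
    }
    (C - D) / sqrt((C + D + Ta) * (C + D + Tb))
}

# literal Benjamini-Hochberg step-up with universe size m
bruteBH <- function(p, m = length(p)) {
    o <- order(p)
    k <- length(p)
    q <- numeric(k)
    for (i in seq_len(k)) {
        cand <- vapply(i:k, function(j) p[o[j]] * m / j, numeric(1))
        q[o[i]] <- min(1, min(cand))
    }
    q
}

# exact two-sided signed-rank p by enumerating all 2^n sign assignments
bruteSignedRankP <- function(d) {
    stopifnot(!any(d == 0), !anyDuplicated(abs(d)))
    n <- length(d)
    r <- rank(abs(d))
    v <- sum(r[d > 0])
    signs <- expand.grid(rep(list(c(0, 1)), n))
    vs <- as.matrix(signs) %*% r
    pl <- mean(vs <= v); pu <- mean(vs >= v)
    min(1, 2 * min(pl, pu))
}

smallConfig <- function(...) {
    args <- list(nGenes = 60L, nSeed = 8L, nBrains = 3L,
                 regions = c(cerebrum_early = 8L, cerebrum_late = 6L,
                             cerebellum = 4L, brain_stem = 4L),
                 samplesPerRegionPerBrain = 1L,
                 nSignalGenes = 3L, rngSeed = 42L)
    args[names(list(...))] <- list(...)
    do.call(simConfig, args)
}
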