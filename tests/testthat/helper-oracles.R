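# Independent oracles used across the suite. These deliberately take the
# slow, literal route (explicit loops, exhaustive summation) so they share
# no code path with the package implementation.

# Composite index by naive double loops over gene pairs.
oracleCompositeIndex <- function(module, expr, samples, epsilon = 1e-6) {
    sub <- expr[, samples, drop = FALSE]
    genes <- rownames(sub)
    outside <- setdiff(genes, module)
    pairCor <- function(g, h) {
        x <- sub[g, ]; y <- sub[h, ]
        if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
        stats::cor(x, y)
    }
    s_in <- 0; n_in <- 0
    for (i in seq_along(module)) for (j in seq_along(module)) {
        if (i < j) {
            s_in <- s_in + abs(pairCor(module[i], module[j]))
            n_in <- n_in + 1
        }
    }
    s_out <- 0; n_out <- 0
    for (g in module) for (h in outside) {
        s_out <- s_out + abs(pairCor(g, h))
        n_out <- n_out + 1
    }
    pcc_in <- s_in / n_in
    pcc_out <- s_out / n_out
    sd_in <- mean(vapply(module, function(g) stats::sd(sub[g, ]), 0))
    list(pcc_in = pcc_in, pcc_out = pcc_out, sd_in = sd_in,
         ci = pcc_in / max(pcc_out, epsilon) * sd_in)
}

# Hypergeometric enrichment tail by explicit summation of the density
# formula (choose terms), not via phyper.
oracleOverlapP <- function(k, sizeA, sizeB, N) {
    kmax <- min(sizeA, sizeB)
    tail <- 0
    for (x in k:kmax) {
        tail <- tail + exp(lchoose(sizeA, x) + lchoose(N - sizeA, sizeB - x) -
                           lchoose(N, sizeB))
    }
    min(tail, 1)
}

# Benjamini-Hochberg step-up by the definition: adj_i = min_{j: p_j >= p_i}
# min(1, m * p_(j) / rank(j)).
oracleBH <- function(p) {
    m <- length(p)
    ord <- order(p)
    adj <- numeric(m)
    running <- 1
    for (r in m:1) {
        i <- ord[r]
        running <- min(running, m * p[i] / r)
        adj[i] <- running
    }
    adj
}

# Mean within-module |PCC| expected from the latent equicorrelated model
# when estimated from nReps samples: Monte-Carlo over many independent
# nReps-sample experiments.
oracleLatentMeanAbsPCC <- function(rho, nGenes, nReps, nSim = 10000,
                                   seed = 1) {
    set.seed(seed)
    tot <- 0
    for (s in seq_len(nSim)) {
        f <- stats::rnorm(nReps)
        x <- sqrt(rho) * matrix(f, nReps, nGenes) +
            sqrt(1 - rho) * matrix(stats::rnorm(nReps * nGenes), nReps)
        cc <- abs(stats::cor(x))
        tot <- tot + (sum(cc) - nGenes) / (nGenes * (nGenes - 1))
    }
    tot / nSim
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# Small default-structure config for fast tests.
smallConfig <- function(...) {
    args <- list(nGenes = 120L, moduleSize = 12L, nAdcMarkers = 8L,
                 nSccMarkers = 8L, nWntMarkers = 5L, seed = 1L)
    args[names(list(...))] <- list(...)
    do.call(syntheticConfig, args)
}

randomExpr <- function(nGenes, nSamples, sd = 1, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    matrix(stats::rnorm(nGenes * nSamples, sd = sd), nGenes, nSamples,
           dimnames = list(sprintf("g%03d", seq_len(nGenes)),
                           sprintf("s%03d", seq_len(nSamples))))
}
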