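test_that("generation is deterministic under a fixed seed", {
    a <- generateTimecourse(smallConfig(seed = 5))
    b <- generateTimecourse(smallConfig(seed = 5))
    expect_identical(a$counts, b$counts)
    expect_identical(a$design, b$design)
    expect_identical(a$truth, b$truth)
    d <- generateTimecourse(smallConfig(seed = 6))
    expect_false(identical(a$counts, d$counts))
})

test_that("config invariants are enforced", {
    expect_error(syntheticConfig(rhoBase = 0.9, rhoPeak = 0.5), "rhoBase")
    expect_error(syntheticConfig(sdInflation = 0.5), "sdInflation")
    expect_error(syntheticConfig(tStarWeeks = 5), "tStarWeeks")
    expect_error(syntheticConfig(nGenes = 50, moduleSize = 40,
                                 nAdcMarkers = 10, nSccMarkers = 10,
                                 nWntMarkers = 5), "exceed")
    # degenerate transition is a legal null configuration
    expect_s4_class(syntheticConfig(rhoBase = 0.2, rhoPeak = 0.2,
                                    sdInflation = 1), "SyntheticConfig")
})

moduleMeanAbsPCC <- function(sim, tce) {
    expr <- logExpr(tce)
    vapply(sort(unique(sim$design$time_weeks)), function(t) {
        s <- sim$design$sample_id[sim$design$time_weeks == t]
        cc <- abs(cor(t(expr[sim$truth$moduleGenes, s])))
        (sum(cc) - nrow(cc)) / (nrow(cc) * (nrow(cc) - 1))
    }, numeric(1))
}

test_that("planted module correlation peaks at t* and matches the latent oracle", {
    # with 6 replicates a single experiment's mean |PCC| is highly variable
    # (all pairs share one factor realization), so the empirical mean is
    # taken over independent experiments before comparing to the oracle
    profs <- sapply(1:15, function(s) {
        sim <- generateTimecourse(smallConfig(seed = s))
        moduleMeanAbsPCC(sim, normalizeRLE(sim$experiment))
    })
    iStar <- 4L  # 7 W among 0/4/6/7/8/9/10
    avg <- rowMeans(profs)
    expect_gt(avg[iStar], max(avg[-iStar]))
    # Monte-Carlo oracle: expected mean |PCC| of the n=6 estimator under the
    # latent equicorrelated model, 10,000 simulated experiments
    oraclePeak <- oracleLatentMeanAbsPCC(0.85, 12, 6, nSim = 10000, seed = 1)
    oracleBase <- oracleLatentMeanAbsPCC(0.2, 12, 6, nSim = 10000, seed = 2)
    # count noise attenuates the generated data slightly below the latent
    # oracle; agreement within 0.1 on the |PCC| scale
    expect_lt(abs(avg[iStar] - oraclePeak), 0.1)
    expect_lt(abs(mean(avg[-iStar]) - oracleBase), 0.1)
})

test_that("a degenerate config plants no correlation or SD peak", {
    cfg <- smallConfig(rhoPeak = 0.2, sdInflation = 1, seed = 3)
    sim <- generateTimecourse(cfg)
    tce <- normalizeRLE(sim$experiment)
    prof <- moduleMeanAbsPCC(sim, tce)
    # the t* value is not systematically extreme: over several seeds the
    # argmax wanders
    argmaxes <- vapply(3:8, function(s) {
        simi <- generateTimecourse(smallConfig(rhoPeak = 0.2,
                                               sdInflation = 1, seed = s))
        tcei <- normalizeRLE(simi$experiment)
        which.max(moduleMeanAbsPCC(simi, tcei))
    }, numeric(1))
    expect_gt(length(unique(argmaxes)), 1)
})

test_that("planted correlation and SD profiles peak at t* across seeds", {
    hits <- vapply(1:20, function(s) {
        sim <- generateTimecourse(smallConfig(seed = s))
        tce <- normalizeRLE(sim$experiment)
        expr <- logExpr(tce)
        corProf <- moduleMeanAbsPCC(sim, tce)
        sdProf <- vapply(sort(unique(sim$design$time_weeks)), function(t) {
            ss <- sim$design$sample_id[sim$design$time_weeks == t]
            mean(apply(expr[sim$truth$moduleGenes, ss], 1, sd))
        }, numeric(1))
        iStar <- sim$truth$tStarIndex
        which.max(corProf) == iStar && which.max(sdProf) == iStar
    }, logical(1))
    expect_gte(mean(hits), 0.9)
})

test_that("marker means switch monotonically in the near-noise-free limit", {
    cfg <- smallConfig(nbDispersion = 0, baseSD = 0.01, seed = 4)
    sim <- generateTimecourse(cfg)
    tce <- normalizeRLE(sim$experiment)
    expr <- logExpr(tce)
    tps <- sort(unique(sim$design$time_weeks))
    adc <- vapply(tps, function(t) {
        s <- sim$design$sample_id[sim$design$time_weeks == t]
        mean(expr[sim$truth$adcMarkers, s])
    }, numeric(1))
    scc <- vapply(tps, function(t) {
        s <- sim$design$sample_id[sim$design$time_weeks == t]
        mean(expr[sim$truth$sccMarkers, s])
    }, numeric(1))
    tol <- 0.05   # residual Poisson/normalization jitter
    expect_true(all(diff(adc) <= tol))
    expect_true(all(diff(scc) >= -tol))
    expect_lt(adc[length(adc)], adc[1] - 2)
    expect_gt(scc[length(scc)], scc[1] + 2)
})

test_that("cohort mixtures reflect their squamous fractions", {
    cfg <- smallConfig(seed = 9)
    # all-adenomatous cohort keeps SCC markers at baseline
    coh0 <- generateAdscCohort(6, rep(0, 6), cfg)
    coh1 <- generateAdscCohort(6, rep(1, 6), cfg)
    expect_gt(mean(coh1$expr[coh1$sccMarkers, ]) -
              mean(coh0$expr[coh0$sccMarkers, ]), 2)
    expect_lt(mean(coh1$expr[coh1$adcMarkers, ]) -
              mean(coh0$expr[coh0$adcMarkers, ]), -2)
    # extreme fractions give well-separated marker centroids
    mix <- generateAdscCohort(10, rep(c(0, 1), 5), cfg)
    diffScore <- colMeans(mix$expr[mix$sccMarkers, ]) -
        colMeans(mix$expr[mix$adcMarkers, ])
    expect_gt(min(diffScore[rep(c(FALSE, TRUE), 5)]),
              max(diffScore[rep(c(TRUE, FALSE), 5)]))
    expect_error(generateAdscCohort(3, c(0, 0.5, 1.2), cfg), "\\[0, 1\\]")
    expect_error(generateAdscCohort(3, c(0, 1), cfg), "one mixture fraction")
})

test_that("truth fraction correlates with the marker-difference readout", {
    cfg <- syntheticConfig(seed = 1)
    set.seed(101)
    fr <- runif(50)
    coh <- generateAdscCohort(50, fr, cfg)
    readout <- colMeans(coh$expr[coh$sccMarkers, ]) -
        colMeans(coh$expr[coh$adcMarkers, ])
    expect_gte(cor(fr, readout, method = "spearman"), 0.9)
})
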