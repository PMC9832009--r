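test_that("pairwise correlations match the closed-form Pearson formula", {
    expr <- rbind(g = c(1, 2, 3), h = c(2, 4, 6), k = c(3, 2, 1),
                  m = c(1, 2, 4), n = c(1, 3, 3))
    colnames(expr) <- paste0("s", 1:3)
    net <- pairwisePCC(expr)
    expect_equal(net@correlations["g", "h"], 1, tolerance = 1e-12)
    expect_equal(net@correlations["g", "k"], -1, tolerance = 1e-12)
    x <- expr["m", ]; y <- expr["n", ]
    r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(net@correlations["m", "n"], r_oracle, tolerance = 1e-12)
    expect_error(pairwisePCC(expr[, 1:2]), "insufficient replicates")
})

test_that("correlation is invariant to positive affine transforms and flags flat genes", {
    expr <- randomExpr(10, 6, seed = 21)
    net <- pairwisePCC(expr)
    expr2 <- expr
    expr2[3, ] <- 5.5 * expr[3, ] + 2
    expr2[7, ] <- 0.1 * expr[7, ] - 30
    net2 <- pairwisePCC(expr2)
    expect_equal(net2@correlations, net@correlations, tolerance = 1e-12)
    expr2[4, ] <- 7   # constant gene
    net3 <- pairwisePCC(expr2)
    expect_identical(net3@zeroVariance, "g004")
    expect_true(all(net3@correlations["g004", -4] == 0))
    expect_equal(net3@correlations["g004", "g004"], 1)
})

test_that("module detection recovers planted blocks and is deterministic", {
    # two perfect blocks of 5, zero cross-correlation
    cc <- diag(20)
    rownames(cc) <- colnames(cc) <- sprintf("g%02d", 1:20)
    cc[1:5, 1:5] <- 1
    cc[6:10, 6:10] <- 1
    diag(cc) <- 1
    net <- new("CorrelationNetwork", correlations = cc, timeLabel = "t",
               zeroVariance = character(0))
    mods <- detectModules(net, minSize = 5, maxSize = 10)
    top2 <- lapply(mods[1:2], members)
    expect_setequal(vapply(top2, function(m) paste(sort(m), collapse = ","),
                           ""),
                    c("g01,g02,g03,g04,g05", "g06,g07,g08,g09,g10"))

    # identity matrix: no cohesive module, but output is deterministic
    idn <- diag(12)
    rownames(idn) <- colnames(idn) <- sprintf("h%02d", 1:12)
    netI <- new("CorrelationNetwork", correlations = idn, timeLabel = "t",
                zeroVariance = character(0))
    m1 <- detectModules(netI, minSize = 5, maxSize = 12)
    m2 <- detectModules(netI, minSize = 5, maxSize = 12)
    expect_identical(lapply(m1, members), lapply(m2, members))
    expect_lt(max(vapply(m1, function(m) m@provenance$cohesion, 0)), 0.5)
})

test_that("top detected block matches exhaustive size-6 subset search", {
    set.seed(8)
    n <- 20
    cc <- matrix(0.05, n, n)
    block <- 3:8
    cc[block, block] <- 0.9
    diag(cc) <- 1
    rownames(cc) <- colnames(cc) <- sprintf("g%02d", 1:n)
    net <- new("CorrelationNetwork", correlations = cc, timeLabel = "t",
               zeroVariance = character(0))
    mods <- detectModules(net, minSize = 5, maxSize = 10)
    sizes <- vapply(mods, function(m) length(members(m)), 0L)
    best6 <- mods[sizes == 6][[1]]            # highest-cohesion size-6 module
    # brute force over all C(20, 6) subsets maximizing mean |PCC|
    A <- abs(cc)
    combos <- utils::combn(n, 6)
    coh <- apply(combos, 2, function(ix)
        (sum(A[ix, ix]) - 6) / (6 * 5))
    oracleBest <- sort(rownames(cc)[combos[, which.max(coh)]])
    expect_identical(sort(members(best6)), oracleBest)
    expect_identical(oracleBest, sort(rownames(cc)[block]))
})

test_that("composite index matches the double-loop oracle exactly", {
    # printed 4-replicate toy: 3-gene module in a 6-gene matrix
    expr <- rbind(a = c(2.0, 2.5, 3.0, 2.2), b = c(1.0, 1.4, 2.1, 1.2),
                  c = c(5.0, 4.2, 4.8, 5.1), d = c(0.5, 0.7, 0.4, 0.9),
                  e = c(3.3, 3.1, 2.9, 3.8), f = c(1.1, 2.2, 3.3, 2.4))
    colnames(expr) <- paste0("r", 1:4)
    got <- compositeIndex(c("a", "b", "c"), expr)
    want <- oracleCompositeIndex(c("a", "b", "c"), expr, colnames(expr))
    for (fld in c("pcc_in", "pcc_out", "sd_in", "ci"))
        expect_equal(got[[fld]], want[[fld]], tolerance = 1e-12)

    # zero-variance module: SDi = 0 hence CI = 0
    expr0 <- expr
    expr0["a", ] <- 1; expr0["b", ] <- 2; expr0["c", ] <- 3
    got0 <- compositeIndex(c("a", "b", "c"), expr0)
    expect_equal(got0$sd_in, 0)
    expect_equal(got0$ci, 0)

    expect_error(compositeIndex(rownames(expr), expr), "whole subspace")
    expect_error(compositeIndex("a", expr), "at least 2")
})

test_that("composite index equals the oracle on random instances (fuzz)", {
    set.seed(33)
    for (i in 1:25) {
        n <- sample(4:15, 1)
        expr <- randomExpr(n, 8)
        k <- sample(2:(n - 1), 1)
        module <- sample(rownames(expr), k)
        got <- compositeIndex(module, expr)
        want <- oracleCompositeIndex(module, expr, colnames(expr))
        expect_equal(got$ci, want$ci, tolerance = 1e-12)
        expect_equal(got$pcc_out, want$pcc_out, tolerance = 1e-12)
        expect_gte(got$ci, 0)
        expect_true(got$pcc_in >= 0 && got$pcc_in <= 1)
    }
})

test_that("dnbScan recovers the planted tipping point on compact panels", {
    sim <- generateTimecourse(smallConfig(seed = 1))
    tce <- normalizeRLE(sim$experiment)
    prof <- dnbScan(tce)
    expect_identical(tippingIndex(prof), sim$truth$tStarIndex)
    expect_identical(tippingTime(prof), 7)
    # dominant module at t* is drawn from the planted module
    expect_gte(mean(dominantModule(prof) %in% sim$truth$moduleGenes), 0.5)
    # subspace restricted to module + 50 background genes: same tipping point
    sub <- c(sim$truth$moduleGenes,
             grep("^BG", rownames(sim$counts), value = TRUE)[1:50])
    prof2 <- dnbScan(tce, subspace = sub)
    expect_identical(tippingTime(prof2), tippingTime(prof))
    # determinism
    prof3 <- dnbScan(tce)
    expect_identical(ciTable(prof3), ciTable(prof))
    expect_identical(prof3@dominantModules, prof@dominantModules)
})

test_that("scan errors are informative", {
    sim <- generateTimecourse(smallConfig(replicatesPerTimepoint = 2L))
    tce <- normalizeRLE(sim$experiment)
    expect_error(dnbScan(tce), "slidingWindowScan")
    expect_error(slidingWindowScan(tce, window = 99L), "exceeds")
    expect_error(slidingWindowScan(tce, window = 0L), ">= 1")
})

test_that("sliding window generalizes the per-timepoint scan", {
    sim <- generateTimecourse(smallConfig(seed = 2))
    tce <- normalizeRLE(sim$experiment)
    w1 <- slidingWindowScan(tce, window = 1L)
    ref <- dnbScan(tce)
    expect_identical(ciTable(w1), ciTable(ref))
    expect_identical(w1@dominantModules, ref@dominantModules)
    # full pooling gives a single evaluation
    nT <- length(unique(sim$design$time_weeks))
    wAll <- slidingWindowScan(tce, window = nT)
    expect_length(wAll@ci, 1)
    # even window labels the later central time point
    w2 <- slidingWindowScan(tce, window = 2L)
    tps <- sort(unique(sim$design$time_weeks))
    expect_identical(w2@timePoints, tps[-1])
})

test_that("sliding window recovers the tipping point with 2 replicates", {
    sim <- generateTimecourse(smallConfig(replicatesPerTimepoint = 2L,
                                          seed = 1))
    tce <- normalizeRLE(sim$experiment)
    prof <- slidingWindowScan(tce, window = 3L)
    expect_identical(tippingTime(prof), 7)
})

test_that("CI is zero iff the module is flat, and never negative", {
    set.seed(55)
    for (i in 1:20) {
        expr <- randomExpr(8, 5)
        module <- sample(rownames(expr), 3)
        ci <- compositeIndex(module, expr)
        expect_gte(ci$ci, 0)
        expect_gt(ci$ci, 0)   # random data: SD > 0 almost surely
        exprFlat <- expr
        exprFlat[module, ] <- matrix(rep(seq_along(module), 5), 3)
        ciFlat <- compositeIndex(module, exprFlat)
        expect_identical(ciFlat$sd_in, 0)
        expect_identical(ciFlat$ci, 0)
    }
})
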