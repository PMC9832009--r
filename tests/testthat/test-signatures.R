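test_that("combined-z scoring reduces correctly in edge cases", {
    expr <- randomExpr(6, 5, seed = 41)
    # singleton set: score equals the gene's z-values
    s1 <- zscoreSignature(expr, geneSet("one", "g002"))
    zref <- (expr["g002", ] - mean(expr["g002", ])) / sd(expr["g002", ])
    expect_equal(scores(s1), zref, tolerance = 1e-12)
    # constant members score 0 everywhere
    exprC <- expr
    exprC["g001", ] <- 3; exprC["g004", ] <- 8
    s0 <- zscoreSignature(exprC, geneSet("flat", c("g001", "g004")))
    expect_true(all(scores(s0) == 0))
    expect_error(zscoreSignature(expr, geneSet("none", c("x1", "x2"))),
                 "missing")
})

test_that("combined-z matches the standardize-sum-scale oracle", {
    expr <- rbind(a = c(1.2, 3.4, 2.0), b = c(5.5, 4.1, 6.0),
                  c = c(0.3, 0.3, 0.9))
    colnames(expr) <- paste0("s", 1:3)
    sc <- zscoreSignature(expr, geneSet("ab", c("a", "b")))
    za <- (expr["a", ] - mean(expr["a", ])) / sd(expr["a", ])
    zb <- (expr["b", ] - mean(expr["b", ])) / sd(expr["b", ])
    expect_equal(scores(sc), (za + zb) / sqrt(2), tolerance = 1e-12)
})

test_that("signature scores have zero mean across samples", {
    expr <- randomExpr(30, 8, seed = 43)
    for (k in c(1, 3, 10)) {
        s <- zscoreSignature(expr, geneSet("s", rownames(expr)[1:k]))
        expect_lt(abs(mean(scores(s))), 1e-9)
    }
})

test_that("differential calling gates on both fold change and adjusted p", {
    set.seed(47)
    expr <- randomExpr(100, 12)
    ga <- colnames(expr)[1:6]; gb <- colnames(expr)[7:12]
    # identical-distribution groups: no calls
    de0 <- deGenes(expr, ga, gb)
    expect_null(de0$up)
    expect_null(de0$down)
    # strong significance but sub-threshold fold change is excluded
    exprFC <- randomExpr(100, 12, sd = 0.01, seed = 48)
    exprFC["g001", 1:6] <- exprFC["g001", 1:6] + log2(1.5)
    deFC <- deGenes(exprFC, ga, gb)
    called <- c(if (!is.null(deFC$up)) members(deFC$up),
                if (!is.null(deFC$down)) members(deFC$down))
    expect_false("g001" %in% called)
    expect_lt(deFC$table$adj_p[deFC$table$gene_id == "g001"], 0.001)
    expect_error(deGenes(expr, ga[1:2], gb), "at least 3")
    expect_error(deGenes(expr, ga, c(gb, ga[1])), "disjoint")
})

test_that("planted fold-change-4 genes are recovered without false positives", {
    expr <- randomExpr(200, 12, sd = 0.2, seed = 49)
    planted <- rownames(expr)[1:10]
    expr[planted, 1:6] <- expr[planted, 1:6] + 2   # log2 fc = 2 -> fc 4
    de <- deGenes(expr, colnames(expr)[1:6], colnames(expr)[7:12])
    expect_setequal(members(de$up), planted)
    expect_null(de$down)
})

test_that("BH adjustment agrees with the step-up oracle", {
    set.seed(51)
    for (i in 1:20) {
        p <- runif(sample(3:20, 1))
        expect_equal(p.adjust(p, method = "BH"), oracleBH(p),
                     tolerance = 1e-12)
    }
})

test_that("AST score cancels, antisymmetrizes, and orders mixtures", {
    expr <- randomExpr(30, 10, seed = 53)
    sA <- geneSet("adc", rownames(expr)[1:5], "up")
    sB <- geneSet("scc", rownames(expr)[11:15], "up")
    same <- astScore(expr, sA, sA)
    expect_true(all(abs(scores(same$ast)) < 1e-12))
    fwd <- astScore(expr, sA, sB)
    rev <- astScore(expr, sB, sA)
    expect_equal(scores(fwd$ast), -scores(rev$ast), tolerance = 1e-15)
    expect_identical(fwd$ordering, names(sort(scores(fwd$ast))))
})

test_that("AST score recovers mixture fractions and the Wnt-like decay", {
    cfg <- syntheticConfig(seed = 1)
    set.seed(99)
    fr <- runif(50)
    coh <- generateAdscCohort(50, fr, cfg)
    res <- astScore(coh$expr, geneSet("adc", coh$adcMarkers, "up"),
                    geneSet("scc", coh$sccMarkers, "up"))
    expect_gte(cor(fr, scores(res$ast)[colnames(coh$expr)],
                   method = "spearman"), 0.9)
    wnt <- zscoreSignature(coh$expr, geneSet("wnt", coh$wntMarkers))
    ct <- correlateWithAST(wnt, res$ast)
    expect_lt(ct$r, 0)
    expect_lt(ct$p, 1e-6)
})

test_that("correlation with AST handles identity, reflection and degeneracy", {
    sc <- new("SignatureScore", setName = "x",
              scores = c(a = 1, b = 3, c = 2, d = 5), method = "gsva_z")
    ast <- new("SignatureScore", setName = "AST",
               scores = c(a = 1, b = 3, c = 2, d = 5), method = "ast")
    expect_equal(correlateWithAST(sc, ast)$r, 1, tolerance = 1e-12)
    neg <- new("SignatureScore", setName = "y",
               scores = -scores(ast), method = "gsva_z")
    expect_equal(correlateWithAST(neg, ast)$r, -1, tolerance = 1e-12)
    flat <- new("SignatureScore", setName = "z",
                scores = c(a = 1, b = 1, c = 1, d = 1), method = "gsva_z")
    expect_true(is.na(correlateWithAST(flat, ast)$r))
})
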