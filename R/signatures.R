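perGeneZ <- function(expr, genes) {
    present <- intersect(genes, rownames(expr))
    if (!length(present))
        stop("no gene-set member present in the matrix; missing: ",
             paste(utils::head(genes, 10L), collapse = ", "))
    sub <- expr[present, , drop = FALSE]
    mu <- rowMeans(sub)
    sd <- apply(sub, 1L, stats::sd)
    z <- (sub - mu) / ifelse(sd > 0, sd, 1)
    z[sd == 0, ] <- 0                        # zero-variance convention
    z
}

#' Gene-set score by the combined-z (GSVA z-score) method
#'
#' Each member gene is standardized across samples (mean 0, SD 1;
#' zero-variance genes contribute 0) and the per-sample score is the sum of
#' member z-values divided by sqrt(k), where k is the number of members
#' present in the matrix.
#'
#' @param object log-expression matrix (genes x samples, >= 2 samples) or a
#'   \linkS4class{TimeCourseExperiment} with a \code{"logexpr"} assay.
#' @param geneSet a \linkS4class{GeneSet}.
#' @param ... passed through between methods.
#' @return a \linkS4class{SignatureScore} with method \code{"gsva_z"}.
#'
#' @examples
#' m <- matrix(rnorm(30), 6, 5,
#'             dimnames = list(paste0("g", 1:6), paste0("s", 1:5)))
#' zscoreSignature(m, geneSet("demo", c("g1", "g2", "g3")))
#' @rdname zscoreSignature
#' @export
setMethod("zscoreSignature", "matrix", function(object, geneSet, ...) {
    if (ncol(object) < 2L) stop("need at least 2 samples")
    z <- perGeneZ(object, members(geneSet))
    sc <- colSums(z) / sqrt(nrow(z))
    new("SignatureScore", setName = setName(geneSet), scores = sc,
        method = "gsva_z")
})

#' @rdname zscoreSignature
#' @export
setMethod("zscoreSignature", "TimeCourseExperiment",
          function(object, geneSet, ...) {
    zscoreSignature(logExpr(object), geneSet, ...)
})

#' Differential gene sets by Welch t-test with BH correction
#'
#' Per-gene Welch (unequal-variance) t-test between two sample groups on
#' normalized log2 values, Benjamini-Hochberg adjustment across all tested
#' genes; a gene is "up" in A when its mean log2 difference (A - B) exceeds
#' log2(fcThreshold) and its adjusted p-value is below alpha, and "down"
#' under the mirrored condition. This simplified test is pluggable:
#' externally computed sets can be supplied anywhere a \code{GeneSet} is
#' accepted.
#'
#' @param expr log-expression matrix.
#' @param groupA,groupB disjoint character vectors of sample ids, at least
#'   3 each.
#' @param fcThreshold fold-change gate on the linear scale (default 2).
#' @param alpha adjusted-p threshold (default 0.001).
#' @return list with \code{up} and \code{down} \linkS4class{GeneSet}s
#'   (either may be empty: then NULL) and \code{table}, the full per-gene
#'   statistics (log2 fold change, t, df, p, adjusted p).
#' @export
deGenes <- function(expr, groupA, groupB, fcThreshold = 2, alpha = 0.001) {
    if (length(groupA) < 3L || length(groupB) < 3L)
        stop("each group needs at least 3 samples")
    if (length(intersect(groupA, groupB)))
        stop("groups must be disjoint")
    a <- expr[, groupA, drop = FALSE]
    b <- expr[, groupB, drop = FALSE]
    na <- ncol(a); nb <- ncol(b)
    ma <- rowMeans(a); mb <- rowMeans(b)
    va <- apply(a, 1L, stats::var); vb <- apply(b, 1L, stats::var)
    se2 <- va / na + vb / nb
    tstat <- (ma - mb) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
    p[se2 == 0] <- 1                          # both groups constant
    adj <- stats::p.adjust(p, method = "BH")
    lfc <- ma - mb
    tab <- data.frame(gene_id = rownames(expr), log2fc = lfc, t = tstat,
                      df = df, p_value = p, adj_p = adj, row.names = NULL)
    thr <- log2(fcThreshold)
    upIds <- tab$gene_id[lfc > thr & adj < alpha]
    dnIds <- tab$gene_id[lfc < -thr & adj < alpha]
    list(up = if (length(upIds)) geneSet("up_in_A", upIds, "up") else NULL,
         down = if (length(dnIds)) geneSet("down_in_A", dnIds, "down")
                else NULL,
         table = tab)
}

#' AST score: squamous-proximity of each sample
#'
#' The ADC score of a sample is the mean of the per-gene standardized
#' expression (z-values, standardized across the cohort) over the genes
#' upregulated in ADC; the SCC score is computed analogously over genes
#' upregulated in SCC; the AST score is SCC score minus ADC score. Sorting
#' samples by AST score orders them from ADC-like to SCC-like.
#'
#' @param object log-expression matrix or \linkS4class{TimeCourseExperiment}.
#' @param adcUp,sccUp \linkS4class{GeneSet}s of ADC- and SCC-upregulated
#'   genes.
#' @param ... passed through between methods.
#' @return list of three \linkS4class{SignatureScore}s (\code{adc} and
#'   \code{scc}, method \code{"mean_z"}; \code{ast}, method \code{"ast"})
#'   and \code{ordering}, sample ids sorted by increasing AST score.
#'
#' @examples
#' m <- matrix(rnorm(40), 8, 5,
#'             dimnames = list(paste0("g", 1:8), paste0("s", 1:5)))
#' res <- astScore(m, geneSet("adc", c("g1", "g2"), "up"),
#'                 geneSet("scc", c("g5", "g6"), "up"))
#' scores(res$ast)
#' @rdname astScore
#' @export
setMethod("astScore", "matrix", function(object, adcUp, sccUp, ...) {
    adc <- colMeans(perGeneZ(object, members(adcUp)))
    scc <- colMeans(perGeneZ(object, members(sccUp)))
    ast <- scc - adc
    list(adc = new("SignatureScore", setName = setName(adcUp), scores = adc,
                   method = "mean_z"),
         scc = new("SignatureScore", setName = setName(sccUp), scores = scc,
                   method = "mean_z"),
         ast = new("SignatureScore", setName = "AST", scores = ast,
                   method = "ast"),
         ordering = names(sort(ast)))
})

#' @rdname astScore
#' @export
setMethod("astScore", "TimeCourseExperiment",
          function(object, adcUp, sccUp, ...) {
    astScore(logExpr(object), adcUp, sccUp, ...)
})

#' Pearson correlation of a signature with the AST score
#'
#' Reports the signed correlation so that "negatively correlated with the
#' AST score" (i.e. the signature decays toward the squamous state) reads
#' directly off the result.
#'
#' @param sig,ast \linkS4class{SignatureScore}s over the same samples
#'   (at least 3).
#' @return list with \code{r}, \code{p} (two-sided, t-distributed),
#'   \code{n}; \code{r} and \code{p} are NA when either score vector has
#'   zero variance.
#' @export
correlateWithAST <- function(sig, ast) {
    s <- scores(sig); a <- scores(ast)
    common <- intersect(names(s), names(a))
    if (length(common) < 3L) stop("need at least 3 shared samples")
    s <- s[common]; a <- a[common]
    if (stats::sd(s) == 0 || stats::sd(a) == 0)
        return(list(r = NA_real_, p = NA_real_, n = length(common)))
    ct <- stats::cor.test(s, a, method = "pearson")
    list(r = unname(ct$estimate), p = ct$p.value, n = length(common))
}
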