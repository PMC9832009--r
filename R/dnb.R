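#' Pearson correlation network at one time point
#'
#' Correlates every gene pair across the replicates of a time point.
#' Genes that are constant across the replicates are flagged and assigned
#' correlation 0 to every partner (their diagonal stays 1).
#'
#' @param expr numeric matrix of normalized log expression, genes x samples,
#'   already restricted to the candidate gene subspace.
#' @param samples column ids (or indices) of the replicates to use; at
#'   least 3 are required.
#' @param timeLabel label stored on the network.
#' @return a \linkS4class{CorrelationNetwork}.
#' @export
pairwisePCC <- function(expr, samples = colnames(expr), timeLabel = "") {
    sub <- expr[, samples, drop = FALSE]
    if (ncol(sub) < 3L)
        stop("insufficient replicates (", ncol(sub), " < 3) for ",
             "correlation estimation; pool time points with ",
             "slidingWindowScan()")
    sds <- apply(sub, 1L, stats::sd)
    flat <- sds == 0 | !is.finite(sds)
    cc <- suppressWarnings(stats::cor(t(sub)))
    cc[flat, ] <- 0
    cc[, flat] <- 0
    cc[!is.finite(cc)] <- 0
    diag(cc) <- 1
    new("CorrelationNetwork", correlations = cc,
        timeLabel = as.character(timeLabel),
        zeroVariance = rownames(sub)[flat])
}

# Clusters under every internal node of an average-linkage dendrogram on
# distance 1 - |PCC|; this is exactly the set of clusters obtainable by
# cutting the tree at each merge height.
enumerateClusters <- function(hc) {
    n <- length(hc$labels)
    nodes <- vector("list", nrow(hc$merge))
    for (i in seq_len(nrow(hc$merge))) {
        pick <- function(j) if (j < 0) hc$labels[-j] else nodes[[j]]
        nodes[[i]] <- c(pick(hc$merge[i, 1L]), pick(hc$merge[i, 2L]))
    }
    nodes
}

#' Detect candidate gene modules in a correlation network
#'
#' Average-linkage hierarchical clustering on distance 1 - |PCC|; the
#' dendrogram is cut at every merge height and each distinct cluster with
#' size in \code{[minSize, maxSize]} is emitted once. Modules are ordered
#' by decreasing mean within-module |PCC| (cohesion); ties are broken by
#' the lexicographically smallest member id. The procedure has no random
#' element: identical inputs give identical output.
#'
#' @param net a \linkS4class{CorrelationNetwork}.
#' @param minSize,maxSize inclusive size bounds (defaults 5 and 200).
#' @param linkage \code{"average"} (default) or \code{"complete"}.
#' @return list of \linkS4class{GeneModule}, best first; empty when the
#'   network has fewer than \code{minSize} genes.
#' @export
detectModules <- function(net, minSize = 5L, maxSize = 200L,
                          linkage = c("average", "complete")) {
    linkage <- match.arg(linkage)
    A <- abs(net@correlations)
    n <- nrow(A)
    if (n < minSize) return(list())
    hc <- stats::hclust(stats::as.dist(1 - A), method = linkage)
    clusters <- enumerateClusters(hc)
    keep <- lengths(clusters) >= minSize & lengths(clusters) <= maxSize
    clusters <- clusters[keep]
    if (!length(clusters)) return(list())
    key <- vapply(clusters, function(m) paste(sort(m), collapse = "\r"),
                  character(1))
    clusters <- clusters[!duplicated(key)]
    cohesion <- vapply(clusters, function(m) {
        k <- length(m)
        (sum(A[m, m]) - k) / (k * (k - 1))
    }, numeric(1))
    minId <- vapply(clusters, function(m) min(m), character(1))
    ord <- order(-cohesion, minId)
    mapply(function(m, coh) {
        new("GeneModule", members = m,
            provenance = list(linkage = linkage, cohesion = coh,
                              timeLabel = net@timeLabel))
    }, clusters[ord], cohesion[ord], SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Composite criticality index of a module at one time point
#'
#' Computes the three DNB criteria and their composite on the replicates of
#' one time point: PCCi, the mean absolute Pearson correlation over
#' unordered within-module gene pairs; PCCo, the mean absolute correlation
#' over module x non-module pairs; SDi, the mean across module genes of
#' the within-timepoint standard deviation of normalized expression; and
#' CI = (PCCi / max(PCCo, epsilon)) * SDi.
#'
#' @param module a \linkS4class{GeneModule} or character vector of gene ids
#'   (at least 2, strictly fewer than the genes of \code{expr}).
#' @param expr numeric matrix (genes x samples) defining the gene subspace.
#' @param samples replicate columns of the time point (>= 3).
#' @param epsilon floor applied to the PCCo denominator.
#' @return named list with elements \code{pcc_in}, \code{pcc_out},
#'   \code{sd_in}, \code{ci}.
#' @export
compositeIndex <- function(module, expr, samples = colnames(expr),
                           epsilon = 1e-6) {
    if (is(module, "GeneModule")) module <- members(module)
    if (length(module) < 2L) stop("module needs at least 2 genes")
    if (!all(module %in% rownames(expr)))
        stop("module gene(s) absent from the matrix")
    if (length(module) >= nrow(expr))
        stop("module spans the whole subspace; PCCo is undefined")
    if (!length(samples)) stop("no samples at this time point")
    net <- pairwisePCC(expr, samples)
    sds <- apply(expr[, samples, drop = FALSE], 1L, stats::sd)
    ciFromNetwork(abs(net@correlations), sds, module, epsilon)
}

# Shared kernel: A = |PCC| matrix over the subspace, sds = per-gene SD at
# the time point (possibly baseline-normalized).
ciFromNetwork <- function(A, sds, module, epsilon) {
    idx <- match(module, rownames(A))
    k <- length(idx)
    inSum <- sum(A[idx, idx]) - k            # off-diagonal within-module sum
    pccIn <- if (k > 1) inSum / (k * (k - 1)) else 0
    nOut <- nrow(A) - k
    outSum <- sum(A[idx, , drop = FALSE]) - k - inSum
    pccOut <- outSum / (k * nOut)
    sdIn <- mean(sds[idx])
    list(pcc_in = pccIn, pcc_out = pccOut, sd_in = sdIn,
         ci = (pccIn / max(pccOut, epsilon)) * sdIn)
}

# Common scan engine: `groups` is a named list mapping a time label to the
# sample ids pooled for that evaluation.
scanCore <- function(expr, groups, labels, minSize, maxSize, linkage,
                     epsilon, sdRelativeToBaseline, method) {
    nT <- length(groups)
    sdMat <- vapply(groups, function(s)
        apply(expr[, s, drop = FALSE], 1L, stats::sd), numeric(nrow(expr)))
    sdUse <- sdMat
    if (sdRelativeToBaseline) {
        ref <- rowMeans(sdMat)
        ref[ref == 0] <- 1                   # constant genes contribute 0/1
        sdUse <- sdMat / ref
    }
    rows <- list()
    pccIn <- pccOut <- sdIn <- ci <- numeric(nT)
    dominant <- vector("list", nT)
    for (ti in seq_len(nT)) {
        net <- pairwisePCC(expr, groups[[ti]], timeLabel = labels[ti])
        A <- abs(net@correlations)
        mods <- detectModules(net, minSize = minSize, maxSize = maxSize,
                              linkage = linkage)
        if (!length(mods))
            stop("no module within the size bounds at time ", labels[ti])
        stats_t <- lapply(mods, function(m)
            ciFromNetwork(A, sdUse[, ti], members(m), epsilon))
        cis <- vapply(stats_t, `[[`, numeric(1), "ci")
        best <- which.max(cis)               # ties: first (highest cohesion)
        s <- stats_t[[best]]
        pccIn[ti] <- s$pcc_in; pccOut[ti] <- s$pcc_out
        sdIn[ti] <- s$sd_in; ci[ti] <- s$ci
        dominant[[ti]] <- members(mods[[best]])
        rows[[ti]] <- data.frame(
            time_weeks = labels[ti],
            module_rank = seq_along(mods),
            size = vapply(mods, function(m) length(members(m)), integer(1)),
            pcc_in = vapply(stats_t, `[[`, numeric(1), "pcc_in"),
            pcc_out = vapply(stats_t, `[[`, numeric(1), "pcc_out"),
            sd_in = vapply(stats_t, `[[`, numeric(1), "sd_in"),
            ci = cis)
    }
    new("CIProfile", timePoints = labels, pccIn = pccIn, pccOut = pccOut,
        sdIn = sdIn, ci = ci, dominantModules = dominant,
        tippingIndex = which.max(ci),        # earliest time wins ties
        moduleTable = do.call(rbind, rows), method = method)
}

resolveSubspace <- function(expr, subspace, topVariableGenes) {
    if (!is.null(subspace)) {
        miss <- setdiff(subspace, rownames(expr))
        if (length(miss))
            stop("subspace gene(s) absent from the matrix: ",
                 paste(utils::head(miss, 5L), collapse = ", "))
        return(expr[subspace, , drop = FALSE])
    }
    k <- min(topVariableGenes, nrow(expr))
    sds <- apply(expr, 1L, stats::sd)
    keep <- names(sort(sds, decreasing = TRUE))[seq_len(k)]
    expr[rownames(expr) %in% keep, , drop = FALSE]   # preserve input order
}

#' Scan a time course for the DNB tipping point
#'
#' For every time point: estimates the replicate-wise Pearson correlation
#' network over the candidate gene subspace, detects modules by
#' deterministic hierarchical clustering, evaluates the composite
#' criticality index CI = (PCCi/PCCo) * SDi for each, and records the
#' max-CI (dominant) module. The tipping point is the time point whose
#' dominant CI is maximal; ties resolve to the earliest time point.
#'
#' @param object a \linkS4class{TimeCourseExperiment} carrying a
#'   \code{"logexpr"} assay (see \code{\link{normalizeRLE}}), or a bare
#'   log-expression matrix (then supply \code{design}).
#' @param design for the matrix method: data.frame with \code{sample_id}
#'   and \code{time_weeks}.
#' @param subspace optional character vector of candidate genes (e.g.
#'   lineage-differential genes); when NULL the \code{topVariableGenes}
#'   most variable genes are used.
#' @param topVariableGenes fallback subspace size (default 2000).
#' @param minReplicates minimum replicates per time point (default 3).
#' @param minSize,maxSize module size bounds passed to
#'   \code{\link{detectModules}}.
#' @param linkage clustering linkage (\code{"average"} default).
#' @param epsilon PCCo denominator floor.
#' @param sdRelativeToBaseline when TRUE each gene's per-timepoint SD is
#'   divided by its mean SD across all time points before averaging into
#'   SDi.
#' @param ... passed through between methods.
#' @return a \linkS4class{CIProfile}.
#'
#' @examples
#' sim <- generateTimecourse(syntheticConfig(nGenes = 120, moduleSize = 12,
#'                                           nWntMarkers = 5, seed = 11))
#' tce <- normalizeRLE(sim$experiment)
#' prof <- dnbScan(tce)
#' tippingTime(prof)
#' @rdname dnbScan
#' @export
setMethod("dnbScan", "TimeCourseExperiment", function(object, ...) {
    design <- data.frame(sample_id = colnames(object),
                         time_weeks = colData(object)$time_weeks)
    dnbScan(logExpr(object), design = design, ...)
})

#' @rdname dnbScan
#' @export
setMethod("dnbScan", "matrix", function(object, design, subspace = NULL,
                                        topVariableGenes = 2000L,
                                        minReplicates = 3L, minSize = 5L,
                                        maxSize = 200L,
                                        linkage = "average",
                                        epsilon = 1e-6,
                                        sdRelativeToBaseline = FALSE, ...) {
    expr <- resolveSubspace(object, subspace, topVariableGenes)
    tps <- sort(unique(design$time_weeks))
    groups <- lapply(tps, function(t)
        design$sample_id[design$time_weeks == t])
    names(groups) <- tps
    short <- lengths(groups) < minReplicates
    if (any(short))
        stop("time point(s) ", paste(tps[short], collapse = ", "),
             " have fewer than ", minReplicates,
             " replicates; use slidingWindowScan() to pool time points")
    scanCore(expr, groups, tps, minSize, maxSize, linkage, epsilon,
             sdRelativeToBaseline, "per_timepoint")
})

#' Sliding-window DNB scan for sparsely replicated series
#'
#' Pools the replicates of \code{window} consecutive time points before
#' network and SD estimation, artificially increasing the number of samples
#' per evaluation; otherwise identical to \code{\link{dnbScan}}. Each window
#' is labeled by its central time point (for an even window, the later of
#' the two central points). \code{window = 1} reproduces \code{dnbScan}
#' exactly.
#'
#' @inheritParams dnbScan
#' @param window number of consecutive time points pooled (>= 1, at most
#'   the number of time points).
#' @return a \linkS4class{CIProfile} with method \code{"sliding_window"}
#'   (or \code{"per_timepoint"} when \code{window = 1}).
#' @rdname slidingWindowScan
#' @export
setMethod("slidingWindowScan", "TimeCourseExperiment", function(object, ...) {
    design <- data.frame(sample_id = colnames(object),
                         time_weeks = colData(object)$time_weeks)
    slidingWindowScan(logExpr(object), design = design, ...)
})

#' @rdname slidingWindowScan
#' @export
setMethod("slidingWindowScan", "matrix",
          function(object, design, window, subspace = NULL,
                   topVariableGenes = 2000L, minSize = 5L, maxSize = 200L,
                   linkage = "average", epsilon = 1e-6,
                   sdRelativeToBaseline = FALSE, ...) {
    tps <- sort(unique(design$time_weeks))
    if (window < 1L) stop("window must be >= 1")
    if (window > length(tps))
        stop("window exceeds the number of time points")
    if (window == 1L)
        return(dnbScan(object, design = design, subspace = subspace,
                       topVariableGenes = topVariableGenes,
                       minSize = minSize, maxSize = maxSize,
                       linkage = linkage, epsilon = epsilon,
                       sdRelativeToBaseline = sdRelativeToBaseline))
    expr <- resolveSubspace(object, subspace, topVariableGenes)
    starts <- seq_len(length(tps) - window + 1L)
    centers <- starts + if (window %% 2L == 1L) (window - 1L) %/% 2L else
        window %/% 2L
    labels <- tps[centers]
    groups <- lapply(starts, function(i) {
        tw <- tps[i:(i + window - 1L)]
        design$sample_id[design$time_weeks %in% tw]
    })
    names(groups) <- labels
    if (any(lengths(groups) < 3L))
        stop("a window pools fewer than 3 samples; enlarge the window")
    scanCore(expr, groups, labels, minSize, maxSize, linkage, epsilon,
             sdRelativeToBaseline, "sliding_window")
})
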