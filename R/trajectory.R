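#' PCA embedding of a temporal expression series
#'
#' Samples are embedded on the first two principal components of the
#' gene-centered (optionally unit-scaled) log-expression matrix. A
#' deterministic sign convention is applied: each component's loading
#' vector is flipped so that its largest-magnitude loading is positive,
#' making embeddings comparable across runs.
#'
#' @param object a \linkS4class{TimeCourseExperiment} with a
#'   \code{"logexpr"} assay, or a genes x samples log-expression matrix.
#' @param scaleGenes scale genes to unit variance before the decomposition
#'   (default FALSE: centering only, preserving high-variance markers'
#'   influence). Constant genes are dropped when scaling.
#' @param ... passed through between methods.
#' @return an \linkS4class{Embedding}.
#'
#' @examples
#' m <- matrix(rnorm(50), 10, 5,
#'             dimnames = list(paste0("g", 1:10), paste0("s", 1:5)))
#' pcaEmbed(m)
#' @rdname pcaEmbed
#' @export
setMethod("pcaEmbed", "matrix", function(object, scaleGenes = FALSE, ...) {
    if (ncol(object) < 3L) stop("PCA needs at least 3 samples")
    x <- t(object)                            # samples x genes
    if (scaleGenes) {
        keep <- apply(object, 1L, stats::sd) > 0
        x <- x[, keep, drop = FALSE]
    }
    pc <- stats::prcomp(x, center = TRUE, scale. = scaleGenes)
    flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
        v <- pc$rotation[, j]
        if (v[which.max(abs(v))] < 0) -1 else 1
    }, numeric(1))
    scoresM <- sweep(pc$x, 2L, flip, "*")
    ve <- pc$sdev^2 / sum(pc$sdev^2)
    nKeep <- min(2L, ncol(scoresM))
    coords <- scoresM[, seq_len(nKeep), drop = FALSE]
    if (nKeep < 2L)
        coords <- cbind(coords, 0)
    colnames(coords) <- c("PC1", "PC2")
    new("Embedding", coordinates = coords,
        varianceExplained = ve)
})

#' @rdname pcaEmbed
#' @export
setMethod("pcaEmbed", "TimeCourseExperiment", function(object, ...) {
    pcaEmbed(logExpr(object), ...)
})

#' Marker expression overlaid on an embedding
#'
#' Min-max scales one gene's expression to [0, 1] and pairs it with the
#' sample coordinates, mirroring trajectory plots colored by relative
#' marker expression. A constant gene maps to 0 for every sample by
#' convention.
#'
#' @param emb an \linkS4class{Embedding}.
#' @param expr the log-expression matrix the embedding came from.
#' @param gene a gene id present in \code{expr}.
#' @return data.frame with columns \code{sample_id}, \code{PC1},
#'   \code{PC2}, \code{relative_expression}.
#' @export
markerOverlay <- function(emb, expr, gene) {
    if (!gene %in% rownames(expr))
        stop("gene '", gene, "' absent from the matrix")
    ids <- rownames(emb@coordinates)
    v <- expr[gene, ids]
    rng <- range(v)
    rel <- if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1])
           else rep(0, length(v))
    data.frame(sample_id = ids,
               PC1 = emb@coordinates[, 1L],
               PC2 = emb@coordinates[, 2L],
               relative_expression = unname(rel),
               row.names = NULL)
}

#' Per-timepoint dispersion of samples in the embedding
#'
#' Quantifies pre-transition instability as the mean Euclidean distance of
#' each time point's samples to their centroid on the first two principal
#' components. Singleton time points have undefined dispersion (NA).
#'
#' @param emb an \linkS4class{Embedding}.
#' @param design data.frame with \code{sample_id} and \code{time_weeks}
#'   covering the embedded samples.
#' @return list with \code{dispersion} (data.frame time_weeks, dispersion,
#'   n) and \code{argmaxTime}, the time point of maximal dispersion.
#' @export
timepointDispersion <- function(emb, design) {
    co <- emb@coordinates
    idx <- match(rownames(co), design$sample_id)
    if (anyNA(idx)) stop("embedding samples missing from the design")
    tw <- design$time_weeks[idx]
    tps <- sort(unique(tw))
    disp <- vapply(tps, function(t) {
        pts <- co[tw == t, , drop = FALSE]
        if (nrow(pts) < 2L) return(NA_real_)
        ctr <- colMeans(pts)
        mean(sqrt(rowSums(sweep(pts, 2L, ctr)^2)))
    }, numeric(1))
    n <- as.integer(table(factor(tw, levels = tps)))
    list(dispersion = data.frame(time_weeks = tps, dispersion = disp, n = n),
         argmaxTime = tps[which.max(disp)])
}
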