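#' Construct a TimeCourseExperiment
#'
#' Bundles a raw count matrix with its serial-sampling design. When both a
#' counts file and a design table are supplied the design's sample order is
#' authoritative: columns of \code{counts} are reordered to match.
#'
#' @param counts non-negative integer matrix, genes in rows (rownames are
#'   gene ids), samples in columns (colnames are sample ids).
#' @param design data.frame with columns \code{sample_id},
#'   \code{time_weeks}, \code{phenotype} (NL/AAH/ADC/SCC/other) and
#'   \code{replicate}, one row per sample of \code{counts}.
#'
#' @return A \linkS4class{TimeCourseExperiment} with a \code{"counts"} assay.
#'
#' @examples
#' cts <- matrix(rpois(12, 50), 3, 4,
#'               dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' des <- data.frame(sample_id = paste0("s", 1:4),
#'                   time_weeks = c(0, 0, 4, 4),
#'                   phenotype = c("NL", "NL", "AAH", "AAH"),
#'                   replicate = c(1, 2, 1, 2))
#' tce <- TimeCourseExperiment(cts, des)
#' @export
TimeCourseExperiment <- function(counts, design) {
    stopifnot(is.matrix(counts))
    if (is.null(rownames(counts)) || is.null(colnames(counts)))
        stop("counts must carry gene and sample ids as dimnames")
    need <- c("sample_id", "time_weeks", "phenotype", "replicate")
    miss <- setdiff(need, colnames(design))
    if (length(miss))
        stop("design lacks column(s): ", paste(miss, collapse = ", "))
    if (anyDuplicated(design$sample_id))
        stop("duplicate sample_id in design")
    if (!setequal(design$sample_id, colnames(counts)))
        stop("design sample ids do not match the count matrix columns")
    counts <- counts[, match(design$sample_id, colnames(counts)), drop = FALSE]
    cd <- DataFrame(time_weeks = as.numeric(design$time_weeks),
                    phenotype = as.character(design$phenotype),
                    replicate = as.integer(design$replicate),
                    row.names = design$sample_id)
    se <- SummarizedExperiment(assays = list(counts = counts), colData = cd)
    new("TimeCourseExperiment", se)
}

#' @rdname accessors
#' @export
setMethod("sizeFactors", "TimeCourseExperiment", function(x, ...) {
    if (!"sizeFactor" %in% colnames(colData(x)))
        stop("no size factors: run normalizeRLE() first")
    stats::setNames(colData(x)$sizeFactor, colnames(x))
})

#' @rdname accessors
#' @export
setMethod("timeWeeks", "TimeCourseExperiment", function(x, ...) {
    stats::setNames(colData(x)$time_weeks, colnames(x))
})

#' Extract the normalized log-expression assay
#'
#' @param x a \linkS4class{TimeCourseExperiment} processed by
#'   \code{\link{normalizeRLE}}.
#' @return numeric matrix of log2(RPM + pseudocount) values.
#' @export
logExpr <- function(x) {
    if (!"logexpr" %in% assayNames(x))
        stop("no 'logexpr' assay: run normalizeRLE() first")
    assay(x, "logexpr")
}

setMethod("show", "TimeCourseExperiment", function(object) {
    callNextMethod()
    tw <- colData(object)$time_weeks
    cat(sprintf("time points (weeks): %s\n",
                paste(sort(unique(tw)), collapse = ", ")))
    tab <- table(tw)
    cat(sprintf("replicates per time point: %s\n",
                paste(as.integer(tab), collapse = ", ")))
})

setMethod("show", "CIProfile", function(object) {
    cat(sprintf("CIProfile (%s) over %d time points\n",
                object@method, length(object@timePoints)))
    print(ciTable(object), digits = 4)
    cat(sprintf("tipping point: index %d (%g weeks), dominant module of %d genes\n",
                object@tippingIndex,
                object@timePoints[object@tippingIndex],
                length(object@dominantModules[[object@tippingIndex]])))
})

#' @rdname accessors
#' @export
setMethod("tippingIndex", "CIProfile", function(x, ...) x@tippingIndex)

#' @rdname accessors
#' @export
setMethod("tippingTime", "CIProfile", function(x, ...)
    x@timePoints[x@tippingIndex])

#' @rdname accessors
#' @export
setMethod("ciTable", "CIProfile", function(x, ...) {
    data.frame(time_weeks = x@timePoints,
               pcc_in = x@pccIn,
               pcc_out = x@pccOut,
               sd_in = x@sdIn,
               ci = x@ci,
               module_size = lengths(x@dominantModules),
               row.names = NULL)
})

#' @rdname accessors
#' @param timeIndex index into the profile's time points; defaults to the
#'   tipping point.
#' @export
setMethod("dominantModule", "CIProfile", function(x, timeIndex = NULL, ...) {
    if (is.null(timeIndex)) timeIndex <- x@tippingIndex
    x@dominantModules[[timeIndex]]
})

#' Create a directional gene set
#'
#' @param name set identifier.
#' @param members gene ids; duplicates are removed, first occurrence kept.
#' @param direction \code{"up"}, \code{"down"} or \code{"unsigned"}.
#' @return a \linkS4class{GeneSet}.
#' @export
geneSet <- function(name, members, direction = "unsigned") {
    new("GeneSet", name = as.character(name),
        members = unique(as.character(members)),
        direction = direction)
}

#' @rdname accessors
#' @export
setMethod("members", "GeneSet", function(x, ...) x@members)

#' @rdname accessors
#' @export
setMethod("members", "GeneModule", function(x, ...) x@members)

setMethod("show", "GeneModule", function(object) {
    cat(sprintf("GeneModule: %d genes (cohesion %.3f)\n",
                length(object@members),
                if (!is.null(object@provenance$cohesion))
                    object@provenance$cohesion else NA_real_))
})

#' @rdname accessors
#' @export
setMethod("setName", "GeneSet", function(x, ...) x@name)

#' @rdname accessors
#' @export
setMethod("setName", "SignatureScore", function(x, ...) x@setName)

#' @rdname accessors
#' @export
setMethod("direction", "GeneSet", function(x, ...) x@direction)

#' @rdname accessors
#' @export
setMethod("scores", "SignatureScore", function(x, ...) x@scores)

setMethod("show", "GeneSet", function(object) {
    cat(sprintf("GeneSet '%s' (%s): %d genes\n", object@name,
                object@direction, length(object@members)))
})

setMethod("show", "SignatureScore", function(object) {
    cat(sprintf("SignatureScore '%s' [%s]: %d samples, range [%.3g, %.3g]\n",
                object@setName, object@method, length(object@scores),
                min(object@scores), max(object@scores)))
})

setMethod("show", "OverlapTestResult", function(object) {
    cat(sprintf(
        "OverlapTestResult: overlap %d | A-only %d | B-only %d | neither %d (N = %d)\n",
        object@overlap, object@onlyA, object@onlyB, object@neither,
        object@universeSize))
    cat(sprintf("odds ratio %.4g%s, %s p = %.4g\n", object@oddsRatio,
                if (object@continuityCorrected) " (0.5 continuity-corrected)" else "",
                object@alternative, object@pValue))
})

setMethod("show", "Embedding", function(object) {
    cat(sprintf("Embedding: %d samples, PC1/PC2 variance explained %.1f%% / %.1f%%\n",
                nrow(object@coordinates),
                100 * object@varianceExplained[1],
                100 * object@varianceExplained[2]))
})

setMethod("show", "SyntheticConfig", function(object) {
    cat(sprintf(
        "SyntheticConfig: %d genes (module %d), %d time points x %d replicates\n",
        object@nGenes, object@moduleSize, length(object@timePointsWeeks),
        object@replicatesPerTimepoint))
    cat(sprintf("tipping point %g W; rho %.2f -> %.2f; SD x%.1f; seed %d\n",
                object@tStarWeeks, object@rhoBase, object@rhoPeak,
                object@sdInflation, object@seed))
})
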