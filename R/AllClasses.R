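#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- assays
#'   assayNames colData colData<-
NULL

PHENOTYPE_LEVELS <- c("NL", "AAH", "ADC", "SCC", "other")

#' TimeCourseExperiment: a temporal expression series
#'
#' A \linkS4class{SummarizedExperiment} whose columns are samples from a
#' serial-sampling design. \code{colData} must carry \code{time_weeks}
#' (non-negative numeric), \code{phenotype} (one of \code{"NL"},
#' \code{"AAH"}, \code{"ADC"}, \code{"SCC"}, \code{"other"}) and
#' \code{replicate} (positive integer). The \code{"counts"} assay holds raw
#' non-negative integer counts; after \code{\link{normalizeRLE}} a
#' \code{"logexpr"} assay holds log2(RPM + pseudocount) values and
#' \code{colData$sizeFactor} the RLE normalization factors.
#'
#' @export
setClass("TimeCourseExperiment", contains = "SummarizedExperiment")

setValidity("TimeCourseExperiment", function(object) {
    msg <- character()
    cd <- colData(object)
    need <- c("time_weeks", "phenotype", "replicate")
    miss <- setdiff(need, colnames(cd))
    if (length(miss))
        return(paste("colData lacks column(s):", paste(miss, collapse = ", ")))
    if (any(is.na(cd$time_weeks)) || any(cd$time_weeks < 0))
        msg <- c(msg, "time_weeks must be non-negative and non-missing")
    if (!all(as.character(cd$phenotype) %in% PHENOTYPE_LEVELS))
        msg <- c(msg, sprintf("phenotype must be one of %s",
                              paste(PHENOTYPE_LEVELS, collapse = "/")))
    rep_ok <- is.numeric(cd$replicate) || is.integer(cd$replicate)
    if (!rep_ok || any(is.na(cd$replicate)) || any(cd$replicate < 1) ||
        any(cd$replicate != round(cd$replicate)))
        msg <- c(msg, "replicate must be a positive integer")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids must be unique")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "gene ids must be unique")
    if ("counts" %in% assayNames(object)) {
        cts <- assay(object, "counts")
        if (any(is.na(cts)) || any(cts < 0))
            msg <- c(msg, "counts must be non-negative and non-missing")
    }
    if (length(msg)) msg else TRUE
})

#' A directional gene set
#'
#' @slot name single character identifier (unique within a collection).
#' @slot members character vector of unique gene ids (non-empty).
#' @slot direction one of \code{"up"}, \code{"down"}, \code{"unsigned"}.
#' @export
setClass("GeneSet", representation(
    name = "character",
    members = "character",
    direction = "character"
))

setValidity("GeneSet", function(object) {
    msg <- character()
    if (length(object@name) != 1L || !nzchar(object@name))
        msg <- c(msg, "name must be a single non-empty string")
    if (length(object@members) < 1L)
        msg <- c(msg, "a gene set needs at least one member")
    if (anyDuplicated(object@members))
        msg <- c(msg, "members must be unique")
    if (length(object@direction) != 1L ||
        !object@direction %in% c("up", "down", "unsigned"))
        msg <- c(msg, "direction must be up/down/unsigned")
    if (length(msg)) msg else TRUE
})

#' Per-sample scalar signature scores
#'
#' @slot setName name of the scored gene set (or \code{"AST"}).
#' @slot scores named numeric vector, one finite score per sample.
#' @slot method scoring method label: \code{"gsva_z"} (combined z,
#'   sum/sqrt(k)), \code{"mean_z"} (plain mean of z-values) or \code{"ast"}.
#' @export
setClass("SignatureScore", representation(
    setName = "character",
    scores = "numeric",
    method = "character"
))

setValidity("SignatureScore", function(object) {
    msg <- character()
    if (is.null(names(object@scores)) || anyDuplicated(names(object@scores)))
        msg <- c(msg, "scores must be named by unique sample ids")
    if (any(!is.finite(object@scores)))
        msg <- c(msg, "scores must be finite")
    if (!object@method %in% c("gsva_z", "mean_z", "ast"))
        msg <- c(msg, "method must be gsva_z/mean_z/ast")
    if (length(msg)) msg else TRUE
})

#' Per-timepoint Pearson correlation network
#'
#' Symmetric gene-by-gene Pearson correlation matrix estimated across the
#' replicates of one time point. Zero-variance genes are assigned
#' correlation 0 to all partners and listed in \code{zeroVariance}.
#'
#' @slot correlations symmetric numeric matrix in [-1, 1], unit diagonal.
#' @slot timeLabel label of the time point (e.g. \code{"7"}).
#' @slot zeroVariance ids of genes flagged as constant across replicates.
#' @export
setClass("CorrelationNetwork", representation(
    correlations = "matrix",
    timeLabel = "character",
    zeroVariance = "character"
))

setValidity("CorrelationNetwork", function(object) {
    m <- object@correlations
    msg <- character()
    if (nrow(m) != ncol(m) || is.null(rownames(m)) ||
        !identical(rownames(m), colnames(m)))
        msg <- c(msg, "correlation matrix must be square with matching dimnames")
    if (anyDuplicated(rownames(m)))
        msg <- c(msg, "gene ids must be unique")
    if (any(abs(m) > 1 + 1e-8, na.rm = TRUE))
        msg <- c(msg, "correlations must lie in [-1, 1]")
    if (max(abs(m - t(m))) > 1e-8)
        msg <- c(msg, "correlation matrix must be symmetric")
    if (max(abs(diag(m) - 1)) > 1e-8)
        msg <- c(msg, "diagonal must be 1")
    if (length(msg)) msg else TRUE
})

#' A candidate DNB gene module
#'
#' @slot members unique gene ids (at least 2).
#' @slot provenance list recording how the module was obtained
#'   (cut height, linkage, cohesion).
#' @export
setClass("GeneModule", representation(
    members = "character",
    provenance = "list"
))

setValidity("GeneModule", function(object) {
    msg <- character()
    if (length(object@members) < 2L)
        msg <- c(msg, "a module needs at least 2 members")
    if (anyDuplicated(object@members))
        msg <- c(msg, "members must be unique")
    if (length(msg)) msg else TRUE
})

#' Composite-index profile over a time course
#'
#' One row per evaluated time point with the dominant (max-CI) module's
#' criticality statistics: PCCi (mean within-module |PCC|), PCCo (mean
#' module-to-outside |PCC|), SDi (mean within-timepoint SD of module genes)
#' and CI = (PCCi / PCCo) * SDi. The tipping point is the time point whose
#' dominant CI is maximal (ties resolved toward the earliest time point).
#'
#' @slot timePoints numeric time labels (weeks) in scan order.
#' @slot pccIn,pccOut,sdIn,ci numeric vectors, one value per time point.
#' @slot dominantModules list of character vectors: the max-CI module at
#'   each time point.
#' @slot tippingIndex integer index into \code{timePoints}.
#' @slot moduleTable data.frame of all candidate modules at all time points
#'   (columns: time_weeks, module, size, pcc_in, pcc_out, sd_in, ci).
#' @slot method \code{"per_timepoint"} or \code{"sliding_window"}.
#' @export
setClass("CIProfile", representation(
    timePoints = "numeric",
    pccIn = "numeric",
    pccOut = "numeric",
    sdIn = "numeric",
    ci = "numeric",
    dominantModules = "list",
    tippingIndex = "integer",
    moduleTable = "data.frame",
    method = "character"
))

setValidity("CIProfile", function(object) {
    n <- length(object@timePoints)
    msg <- character()
    if (!all(lengths(list(object@pccIn, object@pccOut, object@sdIn,
                          object@ci, object@dominantModules)) == n))
        msg <- c(msg, "per-timepoint slots must share one length")
    if (any(object@pccIn < -1e-12 | object@pccIn > 1 + 1e-12, na.rm = TRUE) ||
        any(object@pccOut < -1e-12 | object@pccOut > 1 + 1e-12, na.rm = TRUE))
        msg <- c(msg, "PCCi and PCCo must lie in [0, 1]")
    if (any(object@sdIn < 0, na.rm = TRUE) || any(object@ci < 0, na.rm = TRUE))
        msg <- c(msg, "SDi and CI must be non-negative")
    if (length(object@tippingIndex) != 1L || is.na(object@tippingIndex) ||
        object@tippingIndex < 1L || object@tippingIndex > n)
        msg <- c(msg, "tippingIndex out of range")
    if (length(msg)) msg else TRUE
})

#' Result of a Fisher-exact gene-set overlap test
#'
#' The 2x2 table is (in A and B, A only, B only, neither) over a stated
#' gene universe; the p-value is the one-sided enrichment (hypergeometric
#' upper tail) probability unless \code{alternative} says otherwise.
#'
#' @slot overlap,onlyA,onlyB,neither non-negative integer cell counts.
#' @slot universeSize total number of genes (sum of the four cells).
#' @slot oddsRatio sample odds ratio; a 0.5 continuity correction is applied
#'   only when a margin cell is zero (then \code{continuityCorrected} is TRUE).
#' @slot pValue p-value in (0, 1].
#' @slot adjP BH-adjusted p (NA when tested alone).
#' @slot alternative \code{"greater"} (enrichment) or \code{"two.sided"}.
#' @slot continuityCorrected logical flag.
#' @export
setClass("OverlapTestResult", representation(
    overlap = "integer",
    onlyA = "integer",
    onlyB = "integer",
    neither = "integer",
    universeSize = "integer",
    oddsRatio = "numeric",
    pValue = "numeric",
    adjP = "numeric",
    alternative = "character",
    continuityCorrected = "logical"
))

setValidity("OverlapTestResult", function(object) {
    cells <- c(object@overlap, object@onlyA, object@onlyB, object@neither)
    msg <- character()
    if (any(cells < 0L))
        msg <- c(msg, "cell counts must be non-negative")
    if (sum(cells) != object@universeSize)
        msg <- c(msg, "cells must sum to the universe size")
    if (object@pValue <= 0 || object@pValue > 1)
        msg <- c(msg, "p must lie in (0, 1]")
    if (length(msg)) msg else TRUE
})

#' Configuration of the synthetic critical-transition generator
#'
#' Defaults emulate the serial-sampling study design this package targets:
#' seven sampling times (0, 4, 6, 7, 8, 9, 10 weeks), six replicates each,
#' a planted 30-gene DNB module out of 600 genes whose within-module
#' correlation jumps from 0.2 to 0.85 and whose standard deviation triples
#' at the tipping point (7 weeks), 20 ADC and 20 SCC lineage markers that
#' switch sigmoidally across the transition, and negative-binomial counts.
#'
#' @slot nGenes total genes simulated.
#' @slot moduleSize planted DNB module size.
#' @slot timePointsWeeks sampling times in weeks.
#' @slot replicatesPerTimepoint replicates at each time.
#' @slot tStarWeeks planted tipping point (must be a sampling time).
#' @slot rhoBase within-module correlation away from the tipping point.
#' @slot rhoPeak within-module correlation at the tipping point.
#' @slot sdInflation module SD multiplier at the tipping point.
#' @slot nAdcMarkers,nSccMarkers,nWntMarkers marker-set sizes; the Wnt-like
#'   set decays with squamous content in cohort simulations.
#' @slot switchSteepness sigmoid time constant (weeks) of marker switching.
#' @slot nbDispersion negative-binomial dispersion of the count emission.
#' @slot meanLogExpression range (log2 RPM) for baseline gene means.
#' @slot baseSD latent biological SD (log2 units) away from the transition.
#' @slot backgroundRho correlation among background genes induced by the
#'   shared tissue-level factor.
#' @slot seed root seed; all stage substreams derive from it.
#' @export
setClass("SyntheticConfig", representation(
    nGenes = "integer",
    moduleSize = "integer",
    timePointsWeeks = "numeric",
    replicatesPerTimepoint = "integer",
    tStarWeeks = "numeric",
    rhoBase = "numeric",
    rhoPeak = "numeric",
    sdInflation = "numeric",
    nAdcMarkers = "integer",
    nSccMarkers = "integer",
    nWntMarkers = "integer",
    switchSteepness = "numeric",
    nbDispersion = "numeric",
    meanLogExpression = "numeric",
    baseSD = "numeric",
    backgroundRho = "numeric",
    seed = "integer"
))

setValidity("SyntheticConfig", function(object) {
    msg <- character()
    if (!(object@rhoBase >= 0 && object@rhoBase <= object@rhoPeak &&
          object@rhoPeak < 1))
        msg <- c(msg, "need 0 <= rhoBase <= rhoPeak < 1")
    if (object@sdInflation < 1)
        msg <- c(msg, "sdInflation must be >= 1")
    if (!object@tStarWeeks %in% object@timePointsWeeks)
        msg <- c(msg, "tStarWeeks must be one of timePointsWeeks")
    if (object@moduleSize + object@nAdcMarkers + object@nSccMarkers +
        object@nWntMarkers > object@nGenes)
        msg <- c(msg, "module plus marker genes exceed nGenes")
    if (object@nbDispersion < 0)
        msg <- c(msg, "nbDispersion must be non-negative")
    if (length(object@meanLogExpression) != 2L ||
        diff(object@meanLogExpression) < 0)
        msg <- c(msg, "meanLogExpression must be an increasing range")
    if (object@backgroundRho < 0 || object@backgroundRho >= 1)
        msg <- c(msg, "backgroundRho must lie in [0, 1)")
    if (object@replicatesPerTimepoint < 1L)
        msg <- c(msg, "need at least one replicate per time point")
    if (length(msg)) msg else TRUE
})

#' Two-dimensional PCA embedding of samples
#'
#' @slot coordinates samples x 2 matrix of scores on the first two
#'   principal components (sign-fixed: each loading vector is flipped so its
#'   largest-magnitude entry is positive).
#' @slot varianceExplained fraction of total variance per retained
#'   component, non-increasing, each in [0, 1].
#' @export
setClass("Embedding", representation(
    coordinates = "matrix",
    varianceExplained = "numeric"
))

setValidity("Embedding", function(object) {
    msg <- character()
    if (ncol(object@coordinates) != 2L || is.null(rownames(object@coordinates)))
        msg <- c(msg, "coordinates must be a samples x 2 matrix with rownames")
    ve <- object@varianceExplained
    if (any(ve < -1e-12 | ve > 1 + 1e-12))
        msg <- c(msg, "varianceExplained entries must lie in [0, 1]")
    if (is.unsorted(rev(ve), strictly = FALSE))
        msg <- c(msg, "varianceExplained must be non-increasing")
    if (sum(ve) > 1 + 1e-8)
        msg <- c(msg, "varianceExplained must sum to <= 1")
    if (length(msg)) msg else TRUE
})
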