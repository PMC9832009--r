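#' @rdname normalizeRLE
#' @export
setGeneric("normalizeRLE", function(object, ...) standardGeneric("normalizeRLE"))

#' @rdname dnbScan
#' @export
setGeneric("dnbScan", function(object, ...) standardGeneric("dnbScan"))

#' @rdname slidingWindowScan
#' @export
setGeneric("slidingWindowScan", function(object, ...)
    standardGeneric("slidingWindowScan"))

#' @rdname pcaEmbed
#' @export
setGeneric("pcaEmbed", function(object, ...) standardGeneric("pcaEmbed"))

#' @rdname zscoreSignature
#' @export
setGeneric("zscoreSignature", function(object, geneSet, ...)
    standardGeneric("zscoreSignature"))

#' @rdname astScore
#' @export
setGeneric("astScore", function(object, adcUp, sccUp, ...)
    standardGeneric("astScore"))

#' Accessors for package classes
#'
#' \code{tippingIndex} and \code{tippingTime} report the detected critical
#' time point of a \linkS4class{CIProfile}; \code{ciTable} returns the
#' per-timepoint dominant-module statistics as a data.frame;
#' \code{dominantModule} returns the max-CI module at a given time point
#' (default: the tipping point). \code{members}, \code{setName},
#' \code{direction} access \linkS4class{GeneSet} slots; \code{scores}
#' accesses \linkS4class{SignatureScore}.
#'
#' @param x an object of the documented class.
#' @param ... unused.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("tippingIndex", function(x, ...) standardGeneric("tippingIndex"))

#' @rdname accessors
#' @export
setGeneric("tippingTime", function(x, ...) standardGeneric("tippingTime"))

#' @rdname accessors
#' @export
setGeneric("ciTable", function(x, ...) standardGeneric("ciTable"))

#' @rdname accessors
#' @export
setGeneric("dominantModule", function(x, ...) standardGeneric("dominantModule"))

#' @rdname accessors
#' @export
setGeneric("members", function(x, ...) standardGeneric("members"))

#' @rdname accessors
#' @export
setGeneric("setName", function(x, ...) standardGeneric("setName"))

#' @rdname accessors
#' @export
setGeneric("direction", function(x, ...) standardGeneric("direction"))

#' @rdname accessors
#' @export
setGeneric("scores", function(x, ...) standardGeneric("scores"))

#' @rdname accessors
#' @export
setGeneric("sizeFactors", function(x, ...) standardGeneric("sizeFactors"))

#' @rdname accessors
#' @export
setGeneric("timeWeeks", function(x, ...) standardGeneric("timeWeeks"))
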