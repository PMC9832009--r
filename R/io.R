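#' Read a gene x sample count matrix
#'
#' Expects a delimited text file with a header row: first column gene ids,
#' one column per sample thereafter. Row and column order are preserved.
#'
#' @param path TSV (default) or CSV file.
#' @param sep field separator; \code{","} is auto-detected for \code{.csv}.
#' @return integer matrix with gene ids as rownames, sample ids as colnames.
#' @export
readCounts <- function(path, sep = NULL) {
    if (is.null(sep))
        sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            check.names = FALSE, stringsAsFactors = FALSE,
                            quote = "\"", comment.char = "")
    if (ncol(df) < 2L)
        stop("count file needs a gene-id column plus at least one sample")
    gene_ids <- as.character(df[[1L]])
    if (anyDuplicated(gene_ids))
        stop("duplicate gene ids in count file: ",
             paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
    sample_ids <- colnames(df)[-1L]
    if (anyDuplicated(sample_ids))
        stop("duplicate sample ids in count file header")
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(m))
        stop("non-numeric count entries")
    if (any(is.na(m)) || any(m < 0))
        stop("counts must be non-negative and non-missing")
    if (any(m != round(m)))
        stop("counts must be integers")
    storage.mode(m) <- "integer"
    dimnames(m) <- list(gene_ids, sample_ids)
    m
}

#' Write a count matrix in the format readCounts() expects
#'
#' @param counts integer matrix with dimnames.
#' @param path output TSV path.
#' @param idColumn header of the gene-id column.
#' @export
writeCounts <- function(counts, path, idColumn = "gene_id") {
    df <- data.frame(rownames(counts), counts, check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df)[1L] <- idColumn
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a serial-sampling design table
#'
#' @param path CSV with columns sample_id, time_weeks, phenotype, replicate.
#' @return data.frame with those columns, types coerced and validated.
#' @export
readDesign <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("sample_id", "time_weeks", "phenotype", "replicate")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop("design lacks column(s): ", paste(miss, collapse = ", "))
    if (anyDuplicated(df$sample_id))
        stop("duplicate sample_id in design")
    df$time_weeks <- as.numeric(df$time_weeks)
    df$replicate <- as.integer(df$replicate)
    if (any(is.na(df$time_weeks)) || any(df$time_weeks < 0))
        stop("time_weeks must be non-negative")
    if (!all(df$phenotype %in% PHENOTYPE_LEVELS))
        stop("phenotype must be one of ",
             paste(PHENOTYPE_LEVELS, collapse = "/"))
    df[need]
}

#' Write a design table
#' @param design data.frame as returned by \code{\link{readDesign}}.
#' @param path output CSV path.
#' @export
writeDesign <- function(design, path) {
    utils::write.csv(design, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields
#' \code{name<TAB>description<TAB>member1<TAB>member2...}. Duplicate members
#' within a line are collapsed (first occurrence kept, order preserved).
#'
#' @param path GMT file.
#' @param direction direction label to attach to every set.
#' @return named list of \linkS4class{GeneSet} objects.
#' @export
readGeneSets <- function(path, direction = "unsigned") {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop("empty GMT file")
    sets <- lapply(lines, function(l) {
        f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
        if (length(f) < 3L)
            stop("GMT line with no members: ", f[1L])
        mem <- f[-c(1L, 2L)]
        mem <- mem[nzchar(mem)]
        if (!length(mem))
            stop("GMT set with no members: ", f[1L])
        geneSet(f[1L], mem, direction)
    })
    nms <- vapply(sets, setName, character(1))
    if (anyDuplicated(nms))
        stop("duplicate gene-set names in GMT: ",
             paste(unique(nms[duplicated(nms)]), collapse = ", "))
    stats::setNames(sets, nms)
}

#' Write gene sets to GMT
#' @param sets list of \linkS4class{GeneSet}.
#' @param path output path.
#' @param descriptions optional vector of description-field strings.
#' @export
writeGeneSets <- function(sets, path, descriptions = NULL) {
    if (is.null(descriptions)) descriptions <- rep("na", length(sets))
    lines <- mapply(function(s, d) {
        paste(c(setName(s), d, members(s)), collapse = "\t")
    }, sets, descriptions)
    writeLines(lines, path)
    invisible(path)
}

#' Read a TF -> target map
#'
#' @param path two-column TSV (tf, target), header optional (detected when
#'   the first line is \code{tf<TAB>target}).
#' @return named list: for each TF, a character vector of unique targets.
#' @export
readTFTargets <- function(path) {
    df <- utils::read.table(path, header = FALSE, sep = "\t",
                            stringsAsFactors = FALSE, quote = "",
                            col.names = c("tf", "target"))
    if (nrow(df) &&
        identical(unname(tolower(unlist(df[1, ]))), c("tf", "target")))
        df <- df[-1, , drop = FALSE]
    if (!nrow(df)) stop("empty TF target map")
    map <- lapply(split(df$target, df$tf), unique)
    if (any(lengths(map) < 1L)) stop("TF with empty target set")
    map
}

#' RLE (median-of-ratios) normalization to log2 RPM
#'
#' Estimates per-sample relative-log-expression normalization factors from
#' library-size-scaled counts: for each sample, the factor is the median
#' over reference genes (genes with positive counts in every sample) of the
#' ratio of the sample's count proportion to the gene's geometric-mean
#' proportion, rescaled so the factors have geometric mean 1. The effective
#' library size is library size x factor, and expression is reported as
#' log2(1e6 * count / effective library size + pseudocount).
#'
#' @param object a \linkS4class{TimeCourseExperiment} with a counts assay,
#'   or a bare count matrix.
#' @param pseudocount positive offset on the RPM scale before log2
#'   (default 1, which keeps zero counts at 0).
#' @param ... unused.
#'
#' @return Same class as the input: the experiment gains a \code{"logexpr"}
#'   assay and a \code{sizeFactor} colData column; for a matrix input, a
#'   list with elements \code{logexpr} and \code{sizeFactors}.
#'
#' @examples
#' cts <- matrix(rpois(60, 100), 10, 6,
#'               dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
#' normalizeRLE(cts)$sizeFactors
#' @rdname normalizeRLE
#' @export
setMethod("normalizeRLE", "matrix", function(object, pseudocount = 1, ...) {
    if (pseudocount <= 0) stop("pseudocount must be positive")
    counts <- object
    libsize <- colSums(counts)
    if (any(libsize == 0))
        stop("sample(s) with all-zero counts: ",
             paste(colnames(counts)[libsize == 0], collapse = ", "))
    prop <- sweep(counts, 2L, libsize, "/")
    ref <- rowSums(counts > 0) == ncol(counts)
    if (!any(ref))
        stop("no gene with nonzero counts in every sample; cannot estimate RLE factors")
    refProp <- prop[ref, , drop = FALSE]
    geo <- exp(rowMeans(log(refProp)))
    raw <- apply(refProp / geo, 2L, stats::median)
    sf <- raw / exp(mean(log(raw)))
    efflib <- libsize * sf
    logexpr <- log2(sweep(counts, 2L, efflib, "/") * 1e6 + pseudocount)
    list(logexpr = logexpr, sizeFactors = stats::setNames(sf, colnames(counts)))
})

#' @rdname normalizeRLE
#' @export
setMethod("normalizeRLE", "TimeCourseExperiment",
          function(object, pseudocount = 1, ...) {
    res <- normalizeRLE(assay(object, "counts"), pseudocount = pseudocount)
    assay(object, "logexpr") <- res$logexpr
    colData(object)$sizeFactor <- unname(res$sizeFactors)
    metadata(object)$pseudocount <- pseudocount
    validObject(object)
    object
})
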