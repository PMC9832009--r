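#' Validate a cohort incidence table
#'
#' @param group character vector of cohort names (e.g. genotypes).
#' @param nTotal integer vector: mice per cohort.
#' @param nWithSCC integer vector: mice developing SCC, with
#'   0 <= nWithSCC <= nTotal.
#' @return data.frame with columns \code{group}, \code{n_total},
#'   \code{n_with_scc}.
#'
#' @examples
#' cohortTable(c("KL", "KLC"), c(24, 12), c(4, 12))
#' @export
cohortTable <- function(group, nTotal, nWithSCC) {
    nTotal <- as.integer(nTotal); nWithSCC <- as.integer(nWithSCC)
    if (length(group) != length(nTotal) || length(group) != length(nWithSCC))
        stop("group, nTotal and nWithSCC must have equal length")
    if (any(nTotal < 0L) || any(nWithSCC < 0L))
        stop("counts must be non-negative")
    if (any(nWithSCC > nTotal))
        stop("n_with_scc cannot exceed n_total")
    data.frame(group = as.character(group), n_total = nTotal,
               n_with_scc = nWithSCC, stringsAsFactors = FALSE)
}

# round-half-up to whole percent (matches "17%", "about 33%" reporting)
roundHalfUp <- function(x) floor(x + 0.5)

#' Per-group SCC incidence
#'
#' Incidence = 100 * n_with_scc / n_total, reported both exactly and
#' rounded half-up to the nearest whole percent. Groups with no animals
#' have undefined incidence (NA).
#'
#' @param table a cohort table from \code{\link{cohortTable}}.
#' @return the table extended with \code{incidence_exact} and
#'   \code{incidence_pct} columns.
#'
#' @examples
#' cohortIncidence(cohortTable(c("KL", "KLC", "Nkx2-1"),
#'                             c(24, 12, 12), c(4, 12, 4)))
#' @export
cohortIncidence <- function(table) {
    stopifnot(all(c("group", "n_total", "n_with_scc") %in% colnames(table)))
    if (any(table$n_with_scc > table$n_total) ||
        any(table$n_with_scc < 0) || any(table$n_total < 0))
        stop("invalid cohort counts")
    exact <- ifelse(table$n_total > 0,
                    100 * table$n_with_scc / table$n_total, NA_real_)
    table$incidence_exact <- exact
    table$incidence_pct <- ifelse(is.na(exact), NA_real_, roundHalfUp(exact))
    table
}
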