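#' Fisher-exact overlap of two gene sets within a universe
#'
#' Forms the 2x2 table (in both, A only, B only, neither) over the stated
#' gene universe and computes the one-sided enrichment p-value, i.e. the
#' hypergeometric probability of observing at least the seen overlap given
#' the margins. The universe choice dominates the p-value and must be made
#' explicit by the caller.
#'
#' @param setA,setB character vectors of gene ids, both subsets of
#'   \code{universe} (a \linkS4class{GeneSet} is accepted).
#' @param universe character vector of all considered genes.
#' @param alternative \code{"greater"} (enrichment, default) or
#'   \code{"two.sided"}.
#' @return an \linkS4class{OverlapTestResult}. The odds ratio is the sample
#'   odds ratio; when any cell of the table is zero, 0.5 is added to every
#'   cell first and the result is flagged as continuity-corrected.
#'
#' @examples
#' u <- paste0("g", 1:20)
#' overlapTest(u[1:5], u[c(1:4, 10:13)], u)
#' @export
overlapTest <- function(setA, setB, universe,
                        alternative = c("greater", "two.sided")) {
    alternative <- match.arg(alternative)
    if (is(setA, "GeneSet")) setA <- members(setA)
    if (is(setB, "GeneSet")) setB <- members(setB)
    universe <- unique(universe)
    if (!length(universe)) stop("empty universe")
    setA <- unique(setA); setB <- unique(setB)
    if (!all(setA %in% universe) || !all(setB %in% universe))
        stop("setA and setB must be subsets of the universe")
    N <- length(universe)
    k <- length(intersect(setA, setB))
    a <- length(setA) - k
    b <- length(setB) - k
    d <- N - k - a - b
    p <- if (alternative == "greater") {
        stats::phyper(k - 1L, length(setA), N - length(setA),
                      length(setB), lower.tail = FALSE)
    } else {
        stats::fisher.test(matrix(c(k, a, b, d), 2L),
                           alternative = "two.sided")$p.value
    }
    p <- min(max(p, .Machine$double.xmin), 1)
    cc <- any(c(k, a, b, d) == 0L)
    cells <- c(k, a, b, d) + if (cc) 0.5 else 0
    orat <- (cells[1] * cells[4]) / (cells[2] * cells[3])
    new("OverlapTestResult", overlap = as.integer(k), onlyA = as.integer(a),
        onlyB = as.integer(b), neither = as.integer(d),
        universeSize = as.integer(N), oddsRatio = orat, pValue = p,
        adjP = NA_real_, alternative = alternative,
        continuityCorrected = cc)
}

#' Rank transcription factors by target enrichment in a query set
#'
#' Runs one \code{\link{overlapTest}} per TF (its targets, intersected with
#' the universe, against the query set), adjusts p-values by
#' Benjamini-Hochberg across all TFs, and ranks by descending -log10 p;
#' ties break by descending overlap, then TF id.
#'
#' @param query a \linkS4class{GeneSet} or character vector, subset of the
#'   universe (e.g. genes repressed across the tipping point).
#' @param map named list: TF id -> character vector of target gene ids.
#' @param universe character vector of all considered genes.
#' @param alternative passed to \code{\link{overlapTest}}.
#' @return data.frame (tf, n_targets, overlap, odds_ratio, p_value,
#'   neg_log10_p, adj_p) in rank order.
#' @export
tfEnrichment <- function(query, map, universe, alternative = "greater") {
    if (is(query, "GeneSet")) query <- members(query)
    if (!length(map)) stop("empty TF target map")
    query <- unique(query)
    if (!all(query %in% universe))
        stop("query must be a subset of the universe")
    rows <- lapply(names(map), function(tf) {
        tg <- intersect(unique(map[[tf]]), universe)
        ot <- overlapTest(tg, query, universe, alternative = alternative)
        data.frame(tf = tf, n_targets = length(tg), overlap = ot@overlap,
                   odds_ratio = ot@oddsRatio, p_value = ot@pValue)
    })
    tab <- do.call(rbind, rows)
    tab$neg_log10_p <- -log10(tab$p_value)
    tab$adj_p <- stats::p.adjust(tab$p_value, method = "BH")
    tab[order(-tab$neg_log10_p, -tab$overlap, tab$tf), , drop = FALSE]
}

#' Mutual-suppression ("Yin-Yang") network of lineage TF programs
#'
#' Tests whether two lineage transcription-factor programs counteract each
#' other: every ADC-family TF's target set is tested for enrichment in the
#' genes tuned down by the SCC program (\code{repressed}), and every
#' SCC-family TF against the genes induced by the ADC program
#' (\code{induced}); the two pooled (family-union) cross tests decide the
#' verdict. A "mutual suppression" call is issued when both pooled tests
#' pass \code{alpha} after BH adjustment. The construction is symmetric:
#' exchanging the families while mirroring the induced/repressed sets
#' yields the mirrored graph and the same verdict.
#'
#' @param adcTFs,sccTFs named lists (TF id -> targets), disjoint TF families.
#' @param induced \linkS4class{GeneSet} (or ids): genes induced by the ADC
#'   program.
#' @param repressed \linkS4class{GeneSet} (or ids): genes tuned down by the
#'   SCC program.
#' @param universe character vector of all considered genes.
#' @param alpha verdict threshold on BH-adjusted pooled p-values
#'   (default 0.05).
#' @return list with \code{edges} (data.frame src, dst, overlap,
#'   odds_ratio, p_value, adj_p: per-TF cross-family edges, BH across all
#'   edges), \code{familyTests} (the two pooled tests), and
#'   \code{mutualSuppression} (logical verdict).
#' @export
buildYinyangNetwork <- function(adcTFs, sccTFs, induced, repressed,
                                universe, alpha = 0.05) {
    if (!length(adcTFs) || !length(sccTFs))
        stop("both TF families must be non-empty")
    if (length(intersect(names(adcTFs), names(sccTFs))))
        stop("TF families must be disjoint")
    if (is(induced, "GeneSet")) induced <- members(induced)
    if (is(repressed, "GeneSet")) repressed <- members(repressed)

    edgeRow <- function(tf, targets, dstLabel, dstSet) {
        tg <- intersect(unique(targets), universe)
        ot <- overlapTest(tg, dstSet, universe)
        data.frame(src = tf, dst = dstLabel, overlap = ot@overlap,
                   odds_ratio = ot@oddsRatio, p_value = ot@pValue)
    }
    edges <- rbind(
        do.call(rbind, lapply(names(adcTFs), function(tf)
            edgeRow(tf, adcTFs[[tf]], "SCC_repressed", repressed))),
        do.call(rbind, lapply(names(sccTFs), function(tf)
            edgeRow(tf, sccTFs[[tf]], "ADC_induced", induced))))
    edges$adj_p <- stats::p.adjust(edges$p_value, method = "BH")

    pooled <- rbind(
        edgeRow("ADC_family", unique(unlist(adcTFs)), "SCC_repressed",
                repressed),
        edgeRow("SCC_family", unique(unlist(sccTFs)), "ADC_induced",
                induced))
    pooled$adj_p <- stats::p.adjust(pooled$p_value, method = "BH")

    list(edges = edges, familyTests = pooled,
         mutualSuppression = all(pooled$adj_p < alpha), alpha = alpha)
}

#' Write a counteraction graph as an edge-list TSV
#' @param network result of \code{\link{buildYinyangNetwork}}.
#' @param path output path.
#' @export
writeEdgeList <- function(network, path) {
    utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
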