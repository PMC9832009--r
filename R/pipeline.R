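stageLog <- function(stage, fmt, ...) {
    message(sprintf("[astDNB] %-10s %s", stage, sprintf(fmt, ...)))
}

runStage <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e)
        stop("stage '", stage, "' failed: ", conditionMessage(e),
             call. = FALSE))
    stageLog(stage, "done in %.1fs", proc.time()[["elapsed"]] - t0)
    res
}

#' Run the full tipping-point analysis pipeline
#'
#' Orchestrates simulate (optional) -> normalize -> trajectory -> DNB scan
#' -> signature scoring -> TF network (optional) -> report. Every stage
#' writes its outputs under \code{output_dir} and a JSON manifest records
#' all parameters and seeds so a rerun reproduces the tables exactly.
#'
#' @param config a named list or the path to a YAML file. Recognized
#'   fields: \code{output_dir} (required); \code{seed}; \code{simulate}
#'   (logical or a list of \code{\link{syntheticConfig}} arguments) or
#'   \code{counts}/\code{design} file paths; \code{pseudocount};
#'   \code{subspace} (file with one gene id per line); \code{window}
#'   (sliding-window width, default 1 = per-timepoint scan);
#'   \code{min_size}/\code{max_size} module bounds; \code{adc_set}/
#'   \code{scc_set} (single-set GMT files; defaults to the planted marker
#'   panels when simulating); \code{signatures} (GMT of extra sets to score
#'   and correlate with the AST score); \code{tf_map_adc}/\code{tf_map_scc}
#'   (two-column TSVs) plus \code{induced_set}/\code{repressed_set} (GMTs)
#'   to enable the mutual-suppression stage; \code{cohort_table} (CSV with
#'   group,n_total,n_with_scc).
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
runPipeline <- function(config) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    if (is.null(config$output_dir)) stop("config needs output_dir")
    out <- config$output_dir
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
    outputs <- character(0)
    emit <- function(name, writer) {
        path <- file.path(out, name)
        writer(path)
        outputs <<- c(outputs, path)
        path
    }

    # --- simulate or load -------------------------------------------------
    truth <- NULL
    if (!is.null(config$simulate) && !identical(config$simulate, FALSE)) {
        args <- if (is.list(config$simulate)) config$simulate else list()
        if (is.null(args$seed)) args$seed <- seed
        cfg <- do.call(syntheticConfig, args)
        sim <- runStage("simulate", generateTimecourse(cfg))
        truth <- sim$truth
        counts <- sim$counts; design <- sim$design
        emit("counts.tsv", function(p) writeCounts(counts, p))
        emit("design.csv", function(p) writeDesign(design, p))
        emit("truth.json", function(p)
            jsonlite::write_json(truth, p, auto_unbox = TRUE, digits = NA))
    } else {
        if (is.null(config$counts) || is.null(config$design))
            stop("provide either simulate or counts + design paths")
        counts <- runStage("load", readCounts(config$counts))
        design <- readDesign(config$design)
    }
    tce <- TimeCourseExperiment(counts, design)

    # --- normalize --------------------------------------------------------
    pseudo <- if (is.null(config$pseudocount)) 1 else config$pseudocount
    tce <- runStage("normalize", normalizeRLE(tce, pseudocount = pseudo))
    expr <- logExpr(tce)

    # --- trajectory -------------------------------------------------------
    emb <- runStage("trajectory", pcaEmbed(tce))
    disp <- timepointDispersion(emb, design)
    emit("trajectory_coords.tsv", function(p)
        utils::write.table(
            data.frame(sample_id = rownames(emb@coordinates),
                       emb@coordinates,
                       time_weeks = timeWeeks(tce)[rownames(emb@coordinates)]),
            p, sep = "\t", quote = FALSE, row.names = FALSE))
    emit("trajectory_dispersion.tsv", function(p)
        utils::write.table(disp$dispersion, p, sep = "\t", quote = FALSE,
                           row.names = FALSE))

    # --- DNB scan ---------------------------------------------------------
    subspace <- if (!is.null(config$subspace))
        readLines(config$subspace) else NULL
    window <- if (is.null(config$window)) 1L else as.integer(config$window)
    minSize <- if (is.null(config$min_size)) 5L else
        as.integer(config$min_size)
    maxSize <- if (is.null(config$max_size)) 200L else
        as.integer(config$max_size)
    prof <- runStage("dnb", if (window > 1L)
        slidingWindowScan(tce, window = window, subspace = subspace,
                          minSize = minSize, maxSize = maxSize)
    else
        dnbScan(tce, subspace = subspace, minSize = minSize,
                maxSize = maxSize))
    emit("ci_profile.json", function(p)
        jsonlite::write_json(list(
            method = prof@method,
            time_weeks = prof@timePoints,
            pcc_in = prof@pccIn, pcc_out = prof@pccOut,
            sd_in = prof@sdIn, ci = prof@ci,
            tipping_index = prof@tippingIndex,
            tipping_time_weeks = tippingTime(prof),
            dominant_module = dominantModule(prof)),
            p, auto_unbox = TRUE, digits = NA))
    emit("ci_table.tsv", function(p)
        utils::write.table(prof@moduleTable, p, sep = "\t", quote = FALSE,
                           row.names = FALSE))

    # --- signatures -------------------------------------------------------
    adcSet <- sccSet <- NULL
    if (!is.null(config$adc_set))
        adcSet <- readGeneSets(config$adc_set, "up")[[1L]]
    else if (!is.null(truth))
        adcSet <- geneSet("ADC_markers", truth$adcMarkers, "up")
    if (!is.null(config$scc_set))
        sccSet <- readGeneSets(config$scc_set, "up")[[1L]]
    else if (!is.null(truth))
        sccSet <- geneSet("SCC_markers", truth$sccMarkers, "up")
    scoresRes <- NULL
    if (!is.null(adcSet) && !is.null(sccSet)) {
        scoresRes <- runStage("score", astScore(expr, adcSet, sccSet))
        scoreTab <- data.frame(
            sample_id = names(scores(scoresRes$ast)),
            adc_score = unname(scores(scoresRes$adc)),
            scc_score = unname(scores(scoresRes$scc)),
            ast_score = unname(scores(scoresRes$ast)))
        corTab <- NULL
        extra <- list()
        if (!is.null(config$signatures))
            extra <- readGeneSets(config$signatures)
        else if (!is.null(truth))
            extra <- list(Wnt_like = geneSet("Wnt_like", truth$wntMarkers))
        for (s in extra) {
            sc <- zscoreSignature(expr, s)
            scoreTab[[paste0(setName(s), "_score")]] <- unname(scores(sc))
            ct <- correlateWithAST(sc, scoresRes$ast)
            corTab <- rbind(corTab, data.frame(
                signature = setName(s), r = ct$r, p_value = ct$p))
        }
        if (!is.null(corTab))
            corTab$adj_p <- stats::p.adjust(corTab$p_value, method = "BH")
        emit("scores.tsv", function(p)
            utils::write.table(scoreTab, p, sep = "\t", quote = FALSE,
                               row.names = FALSE))
        if (!is.null(corTab))
            emit("signature_ast_correlations.tsv", function(p)
                utils::write.table(corTab, p, sep = "\t", quote = FALSE,
                                   row.names = FALSE))
    }

    # --- TF network (optional) -------------------------------------------
    network <- NULL
    if (!is.null(config$tf_map_adc) && !is.null(config$tf_map_scc) &&
        !is.null(config$induced_set) && !is.null(config$repressed_set)) {
        adcTFs <- readTFTargets(config$tf_map_adc)
        sccTFs <- readTFTargets(config$tf_map_scc)
        induced <- readGeneSets(config$induced_set)[[1L]]
        repressed <- readGeneSets(config$repressed_set)[[1L]]
        network <- runStage("network",
            buildYinyangNetwork(adcTFs, sccTFs, induced, repressed,
                                universe = rownames(expr)))
        emit("network_edges.tsv", function(p) writeEdgeList(network, p))
    }

    # --- cohort (optional) ------------------------------------------------
    incidence <- NULL
    if (!is.null(config$cohort_table)) {
        ct <- utils::read.csv(config$cohort_table, stringsAsFactors = FALSE)
        incidence <- cohortIncidence(
            cohortTable(ct$group, ct$n_total, ct$n_with_scc))
        emit("cohort_incidence.tsv", function(p)
            utils::write.table(incidence, p, sep = "\t", quote = FALSE,
                               row.names = FALSE))
    }

    manifest <- list(package = "astDNB",
                     version = as.character(utils::packageVersion("astDNB")),
                     seed = seed, config = config,
                     tipping_index = prof@tippingIndex,
                     tipping_time_weeks = tippingTime(prof),
                     outputs = basename(outputs))
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    stageLog("report", "manifest + %d outputs in %s", length(outputs), out)
    invisible(list(experiment = tce, embedding = emb, dispersion = disp,
                   profile = prof, scores = scoresRes, network = network,
                   incidence = incidence, truth = truth,
                   manifest = manifest))
}
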