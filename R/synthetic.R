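# Log2 fold change of the planted lineage-marker switch. ADC markers drop
# and SCC markers rise by this amount across the transition.
MARKER_SWITCH_LOG2FC <- 3

#' Configure the synthetic critical-transition generator
#'
#' Builds a validated \linkS4class{SyntheticConfig}. The defaults define the
#' study conditions every recovery test in this package runs under: a
#' 600-gene panel with a planted 30-gene DNB module, seven sampling times
#' (0/4/6/7/8/9/10 weeks) with six replicates, within-module correlation
#' rising from 0.2 to 0.85 and module SD tripling at the 7-week tipping
#' point, sigmoidally switching ADC/SCC marker panels, and
#' negative-binomial count noise at dispersion 0.1.
#'
#' @param nGenes,moduleSize,timePointsWeeks,replicatesPerTimepoint,tStarWeeks
#'   panel and design geometry; see \linkS4class{SyntheticConfig}.
#' @param rhoBase,rhoPeak,sdInflation planted DNB strength.
#' @param nAdcMarkers,nSccMarkers,nWntMarkers marker panel sizes.
#' @param switchSteepness sigmoid time constant in weeks; 0.35 switches
#'   essentially within one sampling interval.
#' @param nbDispersion negative-binomial dispersion (0 gives Poisson).
#' @param meanLogExpression baseline log2-RPM range genes are drawn from.
#' @param baseSD latent biological SD in log2 units.
#' @param backgroundRho correlation among background genes from the shared
#'   tissue factor; also the module-to-background coupling away from the
#'   tipping point.
#' @param seed integer root seed.
#' @return a \linkS4class{SyntheticConfig}.
#' @export
syntheticConfig <- function(nGenes = 600L, moduleSize = 30L,
                            timePointsWeeks = c(0, 4, 6, 7, 8, 9, 10),
                            replicatesPerTimepoint = 6L, tStarWeeks = 7,
                            rhoBase = 0.2, rhoPeak = 0.85, sdInflation = 3,
                            nAdcMarkers = 20L, nSccMarkers = 20L,
                            nWntMarkers = 15L, switchSteepness = 0.35,
                            nbDispersion = 0.1,
                            meanLogExpression = c(5, 9), baseSD = 0.75,
                            backgroundRho = 0.15, seed = 1L) {
    new("SyntheticConfig",
        nGenes = as.integer(nGenes), moduleSize = as.integer(moduleSize),
        timePointsWeeks = as.numeric(timePointsWeeks),
        replicatesPerTimepoint = as.integer(replicatesPerTimepoint),
        tStarWeeks = as.numeric(tStarWeeks), rhoBase = rhoBase,
        rhoPeak = rhoPeak, sdInflation = sdInflation,
        nAdcMarkers = as.integer(nAdcMarkers),
        nSccMarkers = as.integer(nSccMarkers),
        nWntMarkers = as.integer(nWntMarkers),
        switchSteepness = switchSteepness, nbDispersion = nbDispersion,
        meanLogExpression = as.numeric(meanLogExpression), baseSD = baseSD,
        backgroundRho = backgroundRho, seed = as.integer(seed))
}

# Substream seeds derived from the root so that independent stages do not
# share draws; kept below 2^31.
deriveSeed <- function(seed, offset) {
    as.integer((as.numeric(seed) * 48271 + offset * 9973) %% 2147483647)
}

sigmoidSwitch <- function(t, tStar, steepness) {
    1 / (1 + exp(-(t - tStar) / steepness))
}

phenotypeForTime <- function(t, tStar) {
    ifelse(t == 0, "NL",
           ifelse(t < tStar - 1, "AAH",
                  ifelse(t <= tStar, "ADC", "SCC")))
}

syntheticGeneIds <- function(cfg) {
    nBG <- cfg@nGenes - cfg@moduleSize - cfg@nAdcMarkers - cfg@nSccMarkers -
        cfg@nWntMarkers
    list(module = sprintf("MOD%03d", seq_len(cfg@moduleSize)),
         adc = sprintf("ADC%03d", seq_len(cfg@nAdcMarkers)),
         scc = sprintf("SCC%03d", seq_len(cfg@nSccMarkers)),
         wnt = sprintf("WNT%03d", seq_len(cfg@nWntMarkers)),
         background = sprintf("BG%04d", seq_len(nBG)))
}

# One latent draw (log2 scale) for all genes of one sample.
# Module genes follow an equicorrelated factor model: correlation rhoBase
# away from the tipping point (partly through the shared background factor,
# so they couple to background genes), rhoPeak at the tipping point where
# the background loading is zeroed (realizing the drop in outside
# correlation) and the SD is inflated.
latentSample <- function(cfg, ids, atTStar) {
    # with a degenerate transition (rhoPeak == rhoBase, sdInflation == 1)
    # the tipping-point branch must vanish entirely, giving a true null
    atTStar <- atTStar &&
        (cfg@rhoPeak > cfg@rhoBase || cfg@sdInflation > 1)
    rho <- if (atTStar) cfg@rhoPeak else cfg@rhoBase
    sdMult <- if (atTStar) cfg@sdInflation else 1
    B <- stats::rnorm(1L)                     # shared tissue factor
    F <- stats::rnorm(1L)                     # module factor
    nAll <- cfg@nGenes
    z <- stats::rnorm(nAll)                   # idiosyncratic noise
    names(z) <- c(ids$module, ids$adc, ids$scc, ids$wnt, ids$background)
    bgLoad <- sqrt(cfg@backgroundRho)
    idx_bg <- names(z) %in% ids$background
    z[idx_bg] <- bgLoad * B + sqrt(1 - cfg@backgroundRho) * z[idx_bg]
    idx_mod <- names(z) %in% ids$module
    if (atTStar) {
        z[idx_mod] <- sqrt(rho) * F + sqrt(1 - rho) * z[idx_mod]
    } else {
        a2 <- min(cfg@backgroundRho, rho)     # background coupling
        c2 <- rho - a2                        # module-private coupling
        z[idx_mod] <- sqrt(a2) * B + sqrt(c2) * F +
            sqrt(1 - rho) * z[idx_mod]
    }
    z[idx_mod] <- z[idx_mod] * sdMult
    z * cfg@baseSD
}

nbEmit <- function(mu, dispersion) {
    if (dispersion <= 0) return(stats::rpois(length(mu), mu))
    stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
}

#' Generate a temporal count series with a planted critical transition
#'
#' Simulates multi-timepoint bulk RNA-seq counts in which a gene module
#' exhibits the dynamic-network-biomarker signature at one time point
#' (within-module correlation spikes, correlation to outside genes drops,
#' within-module SD inflates), ADC lineage markers switch off and SCC
#' markers switch on sigmoidally across the transition, and a Wnt-like
#' panel decays alongside the ADC markers. Gene-level log2 means are
#' emitted as negative-binomial counts.
#'
#' @param cfg a \linkS4class{SyntheticConfig}.
#' @return list with elements \code{experiment}
#'   (\linkS4class{TimeCourseExperiment} with the counts assay),
#'   \code{counts} (integer matrix), \code{design} (data.frame) and
#'   \code{truth} (planted module/marker ids, the tipping-point index into
#'   the sorted time points, and the latent per-timepoint correlation and
#'   SD schedule).
#'
#' @examples
#' sim <- generateTimecourse(syntheticConfig(nGenes = 80, moduleSize = 10,
#'                                           nWntMarkers = 5, seed = 7))
#' dim(sim$counts)
#' sim$truth$tStarIndex
#' @export
generateTimecourse <- function(cfg) {
    validObject(cfg)
    ids <- syntheticGeneIds(cfg)
    geneNames <- c(ids$module, ids$adc, ids$scc, ids$wnt, ids$background)
    tps <- sort(unique(cfg@timePointsWeeks))
    nRep <- cfg@replicatesPerTimepoint

    set.seed(deriveSeed(cfg@seed, 1L))
    mu0 <- stats::runif(cfg@nGenes, cfg@meanLogExpression[1L],
                        cfg@meanLogExpression[2L])
    names(mu0) <- geneNames

    sampleIds <- character(0)
    design <- NULL
    countCols <- list()
    for (ti in seq_along(tps)) {
        t <- tps[ti]
        s <- sigmoidSwitch(t, cfg@tStarWeeks, cfg@switchSteepness)
        mu_t <- mu0
        mu_t[ids$adc] <- mu0[ids$adc] + MARKER_SWITCH_LOG2FC * (1 - s)
        mu_t[ids$wnt] <- mu0[ids$wnt] + MARKER_SWITCH_LOG2FC * (1 - s)
        mu_t[ids$scc] <- mu0[ids$scc] + MARKER_SWITCH_LOG2FC * s
        atTStar <- t == cfg@tStarWeeks
        for (r in seq_len(nRep)) {
            z <- latentSample(cfg, ids, atTStar)
            logrpm <- mu_t + z[geneNames]
            depth <- stats::runif(1L, 4e6, 6e6)
            muCount <- 2^logrpm * depth / 1e6
            cts <- nbEmit(muCount, cfg@nbDispersion)
            sid <- sprintf("w%g_r%d", t, r)
            sampleIds <- c(sampleIds, sid)
            countCols[[sid]] <- cts
        }
    }
    counts <- do.call(cbind, countCols)
    rownames(counts) <- geneNames
    storage.mode(counts) <- "integer"

    tw <- rep(tps, each = nRep)
    design <- data.frame(sample_id = sampleIds,
                         time_weeks = tw,
                         phenotype = phenotypeForTime(tw, cfg@tStarWeeks),
                         replicate = rep(seq_len(nRep), times = length(tps)),
                         stringsAsFactors = FALSE)

    truth <- list(
        moduleGenes = ids$module,
        adcMarkers = ids$adc,
        sccMarkers = ids$scc,
        wntMarkers = ids$wnt,
        tStarIndex = match(cfg@tStarWeeks, tps),
        timePointsWeeks = tps,
        latentRho = ifelse(tps == cfg@tStarWeeks, cfg@rhoPeak, cfg@rhoBase),
        latentSD = cfg@baseSD *
            ifelse(tps == cfg@tStarWeeks, cfg@sdInflation, 1))

    list(experiment = TimeCourseExperiment(counts, design),
         counts = counts, design = design, truth = truth)
}

#' Simulate an adenosquamous tumor cohort as ADC/SCC program mixtures
#'
#' Each sample's marker expression is a convex mixture of the pure ADC and
#' pure SCC program profiles: at squamous fraction f, SCC markers sit at
#' baseline + f * switch amplitude, ADC markers (and the decaying Wnt-like
#' panel) at baseline + (1 - f) * amplitude, plus Gaussian noise on the log2
#' scale. Intended for validating AST-score rank recovery.
#'
#' @param nSamples number of tumors.
#' @param mixtureFractions numeric vector in [0, 1], one squamous-program
#'   fraction per sample.
#' @param cfg a \linkS4class{SyntheticConfig} (marker panel sizes, noise and
#'   seed are taken from it).
#' @return list with \code{expr} (log2-scale expression matrix),
#'   \code{fractions} (the truth), and the marker id lists.
#'
#' @examples
#' cfg <- syntheticConfig(nGenes = 100, moduleSize = 10, seed = 3)
#' coh <- generateAdscCohort(10, seq(0, 1, length.out = 10), cfg)
#' @export
generateAdscCohort <- function(nSamples, mixtureFractions, cfg) {
    validObject(cfg)
    if (length(mixtureFractions) != nSamples)
        stop("need one mixture fraction per sample")
    if (any(mixtureFractions < 0 | mixtureFractions > 1))
        stop("mixture fractions must lie in [0, 1]")
    ids <- syntheticGeneIds(cfg)
    geneNames <- c(ids$module, ids$adc, ids$scc, ids$wnt, ids$background)

    set.seed(deriveSeed(cfg@seed, 2L))
    mu0 <- stats::runif(cfg@nGenes, cfg@meanLogExpression[1L],
                        cfg@meanLogExpression[2L])
    names(mu0) <- geneNames
    sampleIds <- sprintf("T%03d", seq_len(nSamples))
    expr <- matrix(0, cfg@nGenes, nSamples,
                   dimnames = list(geneNames, sampleIds))
    for (j in seq_len(nSamples)) {
        f <- mixtureFractions[j]
        mu <- mu0
        mu[ids$adc] <- mu0[ids$adc] + MARKER_SWITCH_LOG2FC * (1 - f)
        mu[ids$wnt] <- mu0[ids$wnt] + MARKER_SWITCH_LOG2FC * (1 - f)
        mu[ids$scc] <- mu0[ids$scc] + MARKER_SWITCH_LOG2FC * f
        expr[, j] <- mu + stats::rnorm(cfg@nGenes, sd = cfg@baseSD)
    }
    list(expr = expr, fractions = mixtureFractions,
         adcMarkers = ids$adc, sccMarkers = ids$scc, wntMarkers = ids$wnt)
}
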