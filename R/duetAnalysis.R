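#' Joint differential expression and splicing analysis
#'
#' The full pipeline: low-count filtering, log2-cpm transformation,
#' mean-variance trends (gene level and isoform level), per-gene MCMC of
#' the hierarchical model, and posterior calls.
#'
#' @param x an \linkS4class{IsoformExperiment} of raw isoform counts.
#' @param minCount per-sample minimum count for \code{\link{filterLowCounts}}
#'   (default 1).
#' @param warmup,steps,chains,seed sampler settings (see
#'   \code{\link{runMCMC}}); defaults 2000 warmup of 10000 total, one
#'   chain.
#' @param threshDE,threshDS classification thresholds (default 0.99).
#' @param isoformLevel use the isoform-level splicing null point (see
#'   \code{\link{posteriorCalls}}).
#' @param geweke if \code{TRUE}, attach a Geweke convergence summary.
#' @return a \linkS4class{DuetResults}.
#' @examples
#' sim <- simulateDataset(simulationConfig(nGenes = 30, seed = 7))
#' res <- duetAnalysis(sim$counts, warmup = 200, steps = 700, seed = 7)
#' head(resultsTable(res))
#' @export
duetAnalysis <- function(x, minCount = 1, warmup = 2000L, steps = 10000L,
                         seed = 1L, chains = 1L, threshDE = 0.99,
                         threshDS = 0.99, isoformLevel = FALSE,
                         geweke = FALSE) {
    x <- filterLowCounts(x, minCount = minCount)
    mi <- buildModelInputs(x)
    pd <- runMCMC(mi, warmup = warmup, steps = steps, seed = seed,
                  chains = chains)
    res <- posteriorCalls(pd, threshDE = threshDE, threshDS = threshDS,
                          isoformLevel = isoformLevel)
    res@settings <- c(res@settings,
                      list(minCount = minCount, warmup = warmup,
                           steps = steps, seed = seed, chains = chains,
                           nGenes = length(mi$genes),
                           nIsoforms = nrow(x)))
    if (geweke)
        res@geweke <- gewekeDiagnostic(pd)
    res
}

#' Run the pipeline on a counts file
#'
#' Reads a TSV of isoform counts (see \code{\link{readIsoformCounts}}),
#' runs \code{\link{duetAnalysis}}, and writes \code{PREFIX.results.tsv}
#' together with \code{PREFIX.log}, a run log recording the settings,
#' filtering summary and Geweke convergence summary.  This is the
#' programmatic core of the \command{duet} command-line script shipped in
#' \code{inst/scripts}.
#'
#' @param countsFile path to the counts TSV.
#' @param nControl number of control samples (leading columns).
#' @param outPrefix output path prefix.
#' @param minCount,warmup,steps,seed,chains,threshDE,threshDS,isoformLevel
#'   passed to \code{\link{duetAnalysis}}.
#' @return the \linkS4class{DuetResults}, invisibly.
#' @export
runPipeline <- function(countsFile, nControl, outPrefix, minCount = 1,
                        warmup = 2000L, steps = 10000L, seed = 1L,
                        chains = 1L, threshDE = 0.99, threshDS = 0.99,
                        isoformLevel = FALSE) {
    x <- readIsoformCounts(countsFile, nControl)
    nIn <- nrow(x)
    res <- duetAnalysis(x, minCount = minCount, warmup = warmup,
                        steps = steps, seed = seed, chains = chains,
                        threshDE = threshDE, threshDS = threshDS,
                        isoformLevel = isoformLevel, geweke = TRUE)
    resPath <- paste0(outPrefix, ".results.tsv")
    writeResults(res, resPath)
    logPath <- paste0(outPrefix, ".log")
    s <- res@settings
    writeLines(c(
        sprintf("counts_file: %s", countsFile),
        sprintf("n_control: %d", nControl),
        sprintf("isoforms_input: %d", nIn),
        sprintf("isoforms_retained: %d", s$nIsoforms),
        sprintf("genes_retained: %d", s$nGenes),
        sprintf("min_count: %g", minCount),
        sprintf("warmup: %d | steps: %d | chains: %d | seed: %d",
                s$warmup, s$steps, s$chains, s$seed),
        sprintf("thresh_de: %g | thresh_ds: %g | isoform_level: %s",
                threshDE, threshDS, isoformLevel),
        sprintf("geweke_frac_bh_significant: %.6f (n = %d)",
                res@geweke$fracSignificant, res@geweke$nTested)),
        logPath)
    invisible(res)
}

#' Write a results table to TSV
#'
#' @param res a \linkS4class{DuetResults}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeResults <- function(res, path) {
    stopifnot(is(res, "DuetResults"))
    write.table(resultsTable(res), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}
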