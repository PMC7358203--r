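#' Simulation configuration
#'
#' Settings for the isoform-level count simulator.  Genes receive expected
#' proportions of the library (log-normal across genes, then normalized),
#' split uniformly across a random number of isoforms.  Differential
#' expression doubles a gene's whole proportion in one randomly chosen
#' condition; differential splicing doubles the proportion of one random
#' isoform in cases and of a different isoform in controls, which leaves
#' the gene's expected total unchanged.  Counts are negative-binomial with
#' a genewise dispersion.
#'
#' @param nGenes number of genes (default 1000).
#' @param nPerGroup samples per condition (default 5).
#' @param libraryMode \code{"equal"} (all libraries at
#'   \code{baseLibrarySize}) or \code{"unequal"} (drawn uniformly from
#'   \code{[base/3, 3*base]}).
#' @param baseLibrarySize expected reads per sample (default 2e6).
#' @param deFraction,dsFraction fractions of genes that are differentially
#'   expressed / spliced (defaults 0.1 each; the sets are disjoint unless
#'   \code{allowOverlap}).
#' @param allowOverlap allow a gene to be both DE and DS (default FALSE).
#' @param dispBase,dispShape,dispScale genewise negative-binomial
#'   dispersion \code{phi = dispBase + 1/Gamma(shape, scale)}; the
#'   defaults (0.1, 10, 25) give dispersions around 0.104, i.e. a
#'   biological coefficient of variation near 0.32.
#' @param geneLogSd standard deviation of the log-normal gene abundance
#'   distribution (default 1.5).
#' @param seed RNG seed (default 1).
#' @return a validated configuration list of class used by
#'   \code{\link{simulateDataset}}.
#' @export
simulationConfig <- function(nGenes = 1000L, nPerGroup = 5L,
                             libraryMode = c("equal", "unequal"),
                             baseLibrarySize = 2e6,
                             deFraction = 0.1, dsFraction = 0.1,
                             allowOverlap = FALSE,
                             dispBase = 0.1, dispShape = 10,
                             dispScale = 25, geneLogSd = 1.5,
                             seed = 1L) {
    libraryMode <- match.arg(libraryMode)
    stopifnot(nGenes >= 1L, nPerGroup >= 2L, baseLibrarySize > 0,
              deFraction >= 0, deFraction <= 1,
              dsFraction >= 0, dsFraction <= 1,
              dispBase >= 0, dispShape > 0, dispScale > 0)
    if (!allowOverlap && deFraction + dsFraction > 1)
        stop("disjoint DE and DS sets need deFraction + dsFraction <= 1")
    list(nGenes = as.integer(nGenes), nPerGroup = as.integer(nPerGroup),
         libraryMode = libraryMode, baseLibrarySize = baseLibrarySize,
         deFraction = deFraction, dsFraction = dsFraction,
         allowOverlap = allowOverlap, dispBase = dispBase,
         dispShape = dispShape, dispScale = dispScale,
         geneLogSd = geneLogSd, seed = as.integer(seed))
}

#' Draw the number of isoforms per gene
#'
#' Each gene receives between 2 and 10 isoforms with probabilities
#' \code{0.4, 0.2, 0.1, 0.05, 0.05, 0.05, 0.05, 0.05, 0.05}.
#'
#' @param nGenes number of genes.
#' @param seed optional seed; when \code{NULL} the current RNG state is
#'   used (as inside \code{\link{simulateDataset}}).
#' @return integer vector of isoform counts.
#' @export
drawIsoformCounts <- function(nGenes, seed = NULL) {
    if (!is.null(seed))
        set.seed(seed)
    sample(2:10, nGenes, replace = TRUE,
           prob = c(0.4, 0.2, 0.1, rep(0.05, 6)))
}

#' Build ground-truth expected proportions
#'
#' Splits each gene's expected proportion evenly over its isoforms, then
#' injects effects: DE genes have every isoform proportion doubled in one
#' randomly chosen condition; DS genes have one random isoform doubled in
#' cases and a different one doubled in controls (so the gene's expected
#' total is unchanged).  Finally the per-condition proportions are
#' renormalized over all isoforms to give the sampling proportions; the
#' pre-renormalization totals and the (renormalization-invariant)
#' within-gene fractions are recorded in the truth table.
#'
#' @param geneProps positive per-gene expected proportions summing to 1.
#' @param Tvec isoform count per gene (all at least 2).
#' @param deGenes,dsGenes integer indices of DE and DS genes.
#' @param seed optional seed (\code{NULL} uses the current RNG state).
#' @param config configuration stored with the truth (optional).
#' @return a \linkS4class{SimulationTruth}.
#' @export
buildTrueProportions <- function(geneProps, Tvec, deGenes, dsGenes,
                                 seed = NULL, config = list()) {
    if (!is.null(seed))
        set.seed(seed)
    nG <- length(geneProps)
    stopifnot(length(Tvec) == nG, all(geneProps > 0), all(Tvec >= 2L),
              abs(sum(geneProps) - 1) < 1e-8)
    genes <- sprintf("gene%04d", seq_len(nG))
    isDE <- seq_len(nG) %in% deGenes
    isDS <- seq_len(nG) %in% dsGenes
    deUpIn <- rep(NA_character_, nG)
    upCase <- rep(NA_character_, nG)
    upCtrl <- rep(NA_character_, nG)

    isoRows <- vector("list", nG)
    totCtrl <- numeric(nG)
    totCase <- numeric(nG)
    for (g in seq_len(nG)) {
        T <- Tvec[g]
        isoIds <- sprintf("%s.iso%d", genes[g], seq_len(T))
        base <- rep(geneProps[g] / T, T)
        propC <- base   # control
        propK <- base   # case
        if (isDE[g]) {
            side <- if (runif(1) < 0.5) "case" else "control"
            deUpIn[g] <- side
            if (side == "case") propK <- propK * 2 else propC <- propC * 2
        }
        if (isDS[g]) {
            ij <- sample.int(T, 2L)
            propK[ij[1L]] <- propK[ij[1L]] * 2
            propC[ij[2L]] <- propC[ij[2L]] * 2
            upCase[g] <- isoIds[ij[1L]]
            upCtrl[g] <- isoIds[ij[2L]]
        }
        totCtrl[g] <- sum(propC)
        totCase[g] <- sum(propK)
        fracC <- propC / totCtrl[g]
        fracK <- propK / totCase[g]
        isoRows[[g]] <- data.frame(
            gene = genes[g], isoform = isoIds,
            frac_control = fracC, frac_case = fracK,
            prop_control = propC, prop_case = propK,
            splicing_fc = fracK / fracC)
    }
    iso <- do.call(rbind, isoRows)
    rownames(iso) <- NULL
    iso$is_ds_isoform <- abs(log2(iso$splicing_fc)) > 1e-12
    # condition-wise renormalization over all isoforms -> sampling props
    iso$prop_control <- iso$prop_control / sum(iso$prop_control)
    iso$prop_case <- iso$prop_case / sum(iso$prop_case)
    geneTab <- data.frame(
        gene = genes, n_isoforms = Tvec, is_de = isDE,
        de_up_in = deUpIn, is_ds = isDS,
        iso_up_case = upCase, iso_up_control = upCtrl,
        total_prop_control = totCtrl, total_prop_case = totCase)
    new("SimulationTruth", genes = geneTab, isoforms = iso,
        config = config)
}

#' Sample negative-binomial counts from a truth table
#'
#' Expected counts are \code{library_size * sampling_proportion} per
#' condition; counts are negative-binomial with a genewise dispersion
#' \code{phi} drawn once per gene as
#' \code{dispBase + 1/Gamma(dispShape, scale = dispScale)}
#' (\code{size = 1/phi}).  Control samples come first.
#'
#' @param truth a \linkS4class{SimulationTruth}.
#' @param config a \code{\link{simulationConfig}}.
#' @param seed optional seed (\code{NULL} uses the current RNG state).
#' @return an \linkS4class{IsoformExperiment}.
#' @export
sampleCounts <- function(truth, config, seed = NULL) {
    if (!is.null(seed))
        set.seed(seed)
    stopifnot(is(truth, "SimulationTruth"))
    iso <- truth@isoforms
    n <- config$nPerGroup
    nLib <- 2L * n
    libs <- if (config$libraryMode == "equal")
        rep(config$baseLibrarySize, nLib)
    else
        runif(nLib, config$baseLibrarySize / 3, 3 * config$baseLibrarySize)
    phi <- config$dispBase +
        1 / rgamma(nrow(truth@genes), shape = config$dispShape,
                   scale = config$dispScale)
    sizeIso <- rep(1 / phi, truth@genes$n_isoforms)
    cts <- matrix(0, nrow(iso), nLib)
    for (s in seq_len(nLib)) {
        prop <- if (s <= n) iso$prop_control else iso$prop_case
        cts[, s] <- rnbinom(nrow(iso), mu = libs[s] * prop, size = sizeIso)
    }
    dimnames(cts) <- list(iso$isoform,
                          c(sprintf("ctrl%d", seq_len(n)),
                            sprintf("case%d", seq_len(n))))
    IsoformExperiment(cts, geneIds = iso$gene,
                      condition = rep(c("control", "case"), each = n))
}

#' Simulate a complete dataset with ground truth
#'
#' Composes \code{\link{drawIsoformCounts}},
#' \code{\link{buildTrueProportions}} and \code{\link{sampleCounts}} under
#' a single seed: gene expected proportions are log-normal
#' (\code{sdlog = geneLogSd}) normalized to sum 1; DE and DS genes are
#' sampled at the configured fractions (disjoint by default).
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return list with \code{counts} (an \linkS4class{IsoformExperiment})
#'   and \code{truth} (a \linkS4class{SimulationTruth}).
#' @examples
#' sim <- simulateDataset(simulationConfig(nGenes = 50, seed = 1))
#' sim$counts
#' sim$truth
#' @export
simulateDataset <- function(config = simulationConfig()) {
    set.seed(config$seed)
    nG <- config$nGenes
    Tvec <- drawIsoformCounts(nG)
    w <- rlnorm(nG, meanlog = 0, sdlog = config$geneLogSd)
    geneProps <- w / sum(w)
    nDE <- round(config$deFraction * nG)
    nDS <- round(config$dsFraction * nG)
    if (config$allowOverlap) {
        deGenes <- sample.int(nG, nDE)
        dsGenes <- sample.int(nG, nDS)
    } else {
        pick <- sample.int(nG, nDE + nDS)
        deGenes <- pick[seq_len(nDE)]
        dsGenes <- pick[nDE + seq_len(nDS)]
    }
    truth <- buildTrueProportions(geneProps, Tvec, deGenes, dsGenes,
                                  config = config)
    counts <- sampleCounts(truth, config)
    list(counts = counts, truth = truth)
}

#' Write a simulated dataset to TSV files
#'
#' \code{PREFIX.counts.tsv} follows the input format of
#' \code{\link{readIsoformCounts}} (Gene, Isoform, control samples first);
#' \code{PREFIX.truth.genes.tsv} and \code{PREFIX.truth.isoforms.tsv} hold
#' the ground truth.
#'
#' @param sim result of \code{\link{simulateDataset}}.
#' @param prefix output path prefix.
#' @return the three file paths, invisibly.
#' @export
writeSimulation <- function(sim, prefix) {
    cts <- SummarizedExperiment::assay(sim$counts, "counts")
    tab <- data.frame(Gene = geneIds(sim$counts),
                      Isoform = isoformIds(sim$counts), cts,
                      check.names = FALSE)
    paths <- paste0(prefix, c(".counts.tsv", ".truth.genes.tsv",
                              ".truth.isoforms.tsv"))
    write.table(tab, paths[1L], sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(truthGenes(sim$truth), paths[2L], sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(truthIsoforms(sim$truth), paths[3L], sep = "\t",
                quote = FALSE, row.names = FALSE)
    invisible(paths)
}
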