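#' Assemble per-gene model inputs
#'
#' Prepares everything the sampler needs: the gene-level matrix (isoform
#' counts summed per gene) and its log2-cpm values, the isoform log2-cpm
#' values, per-observation variances from two independently fitted
#' mean-variance trends (gene level and isoform level), the observed mean
#' control log2-cpm of each gene (the prior centre for \code{beta0}), and
#' the condition labels.  The isoform-level log2-cpm uses the same library
#' sizes as the gene level (the per-sample totals of all isoform counts).
#'
#' Genes with a single isoform get an expression-only block: the splicing
#' parameters are undefined for them.
#'
#' @param x an \linkS4class{IsoformExperiment} (filtered counts; no
#'   \code{"logcpm"} assay required, it is computed here).
#' @param span,iterations LOWESS parameters passed to
#'   \code{\link{fitVarianceTrend}}.
#' @return a list with elements \code{genes} (named list of per-gene input
#'   lists), \code{geneTrend}, \code{isoformTrend}, \code{condition}.
#' @export
buildModelInputs <- function(x, span = 0.5, iterations = 3L) {
    stopifnot(is(x, "IsoformExperiment"))
    cond <- conditionLabels(x)
    if (any(table(cond) < 2L))
        stop("both conditions need at least 2 samples")
    libs <- librarySizes(x)
    x <- cpmLogTransform(x, librarySizes = libs)
    gx <- cpmLogTransform(geneLevelSum(x), librarySizes = libs)

    geneTrend <- fitVarianceTrend(gx, span = span, iterations = iterations)
    isoTrend <- fitVarianceTrend(x, span = span, iterations = iterations)
    vGene <- observationVariances(geneTrend, gx)
    vIso <- observationVariances(isoTrend, x)

    lg <- logCpm(gx)
    li <- logCpm(x)
    ctrl <- cond == "control"
    isCase <- !ctrl
    ids <- geneIds(x)
    rowIdx <- split(seq_len(nrow(x)), factor(ids, levels = rownames(gx)))

    genes <- lapply(rownames(gx), function(g) {
        idx <- rowIdx[[g]]
        Tn <- length(idx)
        if (any(!is.finite(lg[g, ])) || any(!is.finite(li[idx, ])))
            stop(sprintf("non-finite log2-cpm for gene '%s'", g))
        list(gene = g, T = Tn,
             isoform_ids = rownames(x)[idx],
             yg = lg[g, ], vg = vGene[g, ],
             tr = if (Tn >= 2L) li[idx, , drop = FALSE] else
                 matrix(0, 0L, ncol(x)),
             viso = if (Tn >= 2L) vIso[idx, , drop = FALSE] else
                 matrix(0, 0L, ncol(x)),
             mu1 = mean(lg[g, ctrl]),
             isCase = isCase)
    })
    names(genes) <- rownames(gx)
    list(genes = genes, geneTrend = geneTrend, isoformTrend = isoTrend,
         condition = cond)
}

#' Initial values for one gene's chain
#'
#' \code{beta} starts at 0; \code{beta0} at the observed mean control
#' log2-cpm of the gene; the control fractions at the observed fractions
#' \code{2^tr_i / sum_j 2^tr_j} computed from the mean control log2-cpm of
#' each isoform; and \code{alpha} at the uniform identity \code{1/T}.
#'
#' @param gi one element of \code{buildModelInputs(...)$genes}.
#' @return list with \code{beta0}, \code{beta}, \code{p}, \code{alpha}
#'   (\code{p}/\code{alpha} are \code{NULL} for single-isoform genes).
#' @export
initializeChain <- function(gi) {
    out <- list(beta0 = gi$mu1, beta = 0)
    if (gi$T >= 2L) {
        trBar <- rowMeans(gi$tr[, !gi$isCase, drop = FALSE])
        w <- 2^trBar
        out$p <- w / sum(w)
        out$alpha <- uniformAlpha(gi$T)
    } else {
        out$p <- NULL
        out$alpha <- NULL
    }
    out
}

#' Run MCMC for all genes
#'
#' Genes are conditionally independent given the variance trends, so each
#' gene's posterior is sampled separately with a Metropolis-within-Gibbs
#' scheme: the expression parameters \code{(beta0, beta)} are drawn exactly
#' from their bivariate normal full conditional, while the simplex vectors
#' \code{p} and \code{alpha} are updated by random-walk Metropolis on
#' additive-log-ratio coordinates, with step sizes adapted during warmup.
#' Runs are deterministic given \code{seed}.
#'
#' @param mi model inputs from \code{\link{buildModelInputs}}.
#' @param warmup number of warmup (discarded, adaptation) iterations.
#' @param steps total iterations; \code{steps - warmup} draws are kept.
#' @param seed integer RNG seed.
#' @param chains number of independent chains (draws are concatenated;
#'   the Geweke diagnostic should be run on single-chain draws).
#' @param sweeps composition-block Metropolis sweeps per stored iteration
#'   (default 3); extra sweeps reduce the autocorrelation of the
#'   \code{p}/\code{alpha} chains at modest cost.
#' @return a \linkS4class{PosteriorDraws}.
#' @examples
#' sim <- simulateDataset(simulationConfig(nGenes = 30, seed = 1))
#' mi <- buildModelInputs(filterLowCounts(sim$counts))
#' pd <- runMCMC(mi, warmup = 200, steps = 700, seed = 1)
#' pd
#' @export
runMCMC <- function(mi, warmup = 2000L, steps = 10000L, seed = 1L,
                    chains = 1L, sweeps = 3L) {
    warmup <- as.integer(warmup); steps <- as.integer(steps)
    seed <- as.integer(seed); chains <- as.integer(chains)
    sweeps <- max(1L, as.integer(sweeps))
    if (warmup < 1L || steps <= warmup)
        stop("need warmup >= 1 and steps > warmup")
    set.seed(seed)
    lowAcc <- character()
    draws <- lapply(mi$genes, function(gi) {
        # isoform observations centered on the observed gene log2-cpm
        dIso <- if (gi$T >= 2L) gi$tr - rep(gi$yg, each = gi$T) else gi$tr
        # random-walk mixing slows with dimension: give wide simplices
        # proportionally more composition sweeps
        sweepsEff <- max(sweeps, gi$T - 2L)
        perChain <- lapply(seq_len(chains), function(ch) {
            init <- initializeChain(gi)
            .geneSampler(gi$yg, gi$vg, dIso, gi$viso, gi$isCase,
                         gi$mu1, warmup, steps, sweepsEff,
                         if (is.null(init$p)) numeric() else init$p)
        })
        res <- perChain[[1L]]
        if (chains > 1L) {
            res$beta0 <- unlist(lapply(perChain, `[[`, "beta0"))
            res$beta <- unlist(lapply(perChain, `[[`, "beta"))
            if (gi$T >= 2L) {
                res$p <- do.call(rbind, lapply(perChain, `[[`, "p"))
                res$alpha <- do.call(rbind, lapply(perChain, `[[`, "alpha"))
            }
        }
        if (gi$T >= 2L) {
            colnames(res$p) <- colnames(res$alpha) <- gi$isoform_ids
            res$isoform_ids <- gi$isoform_ids
        }
        res
    })
    diag <- data.frame(
        gene = names(draws),
        accept_p = vapply(draws, function(d)
            if (is.null(d$accept_p)) NA_real_ else d$accept_p, 0),
        accept_alpha = vapply(draws, function(d)
            if (is.null(d$accept_alpha)) NA_real_ else d$accept_alpha, 0),
        row.names = NULL)
    slow <- !is.na(diag$accept_p) &
        (diag$accept_p < 0.05 | diag$accept_alpha < 0.05)
    if (any(slow))
        warning(sprintf("low Metropolis acceptance (< 5%%) for %d gene(s): %s",
                        sum(slow),
                        paste(utils::head(diag$gene[slow], 5L),
                              collapse = ", ")))
    new("PosteriorDraws", draws = draws, warmup = warmup, steps = steps,
        seed = seed, diagnostics = diag)
}

#' Geweke convergence diagnostic
#'
#' Compares the mean of an early chain segment with the mean of a late
#' segment, standardized by spectral-density standard errors:
#' \code{z = (m_first - m_last) / sqrt(se_first^2 + se_last^2)}.  The
#' spectral-density standard errors are those of
#' \code{coda::geweke.diag}, and two-sided normal p-values are
#' reported per parameter together with the fraction significant after
#' Benjamini-Hochberg adjustment at 0.05.
#'
#' @param x a \linkS4class{PosteriorDraws} (all scalar parameters of all
#'   genes are tested) or a numeric vector (a single chain).
#' @param firstFrac,lastFrac fractions of the chain used for the early and
#'   late segments (defaults 0.1 and 0.5).
#' @return for a vector, a list with \code{z} and \code{p}; for
#'   \linkS4class{PosteriorDraws}, a list with a per-parameter data.frame
#'   \code{table} (\code{gene}, \code{parameter}, \code{z}, \code{p}),
#'   \code{fracSignificant} (BH at 0.05) and \code{nTested}.  Parameters
#'   with a degenerate (constant) segment are reported as \code{NA} with a
#'   warning and excluded from the adjusted fraction.
#' @export
gewekeDiagnostic <- function(x, firstFrac = 0.1, lastFrac = 0.5) {
    if (firstFrac <= 0 || lastFrac <= 0 || firstFrac + lastFrac >= 1)
        stop("need 0 < firstFrac + lastFrac < 1")
    if (is.numeric(x))
        return(gewekeZ(x, firstFrac, lastFrac))
    stopifnot(is(x, "PosteriorDraws"))
    rows <- list()
    for (g in names(x@draws)) {
        d <- x@draws[[g]]
        pars <- list(beta0 = d$beta0, beta = d$beta)
        if (!is.null(d$p)) {
            for (i in seq_len(ncol(d$p))) {
                pars[[paste0("p[", i, "]")]] <- d$p[, i]
                pars[[paste0("alpha[", i, "]")]] <- d$alpha[, i]
            }
        }
        zp <- lapply(pars, gewekeZ, firstFrac = firstFrac,
                     lastFrac = lastFrac)
        rows[[g]] <- data.frame(
            gene = g, parameter = names(pars),
            z = vapply(zp, `[[`, 0, "z"),
            p = vapply(zp, `[[`, 0, "p"), row.names = NULL)
    }
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    if (anyNA(tab$p))
        warning(sprintf("%d parameter(s) had a degenerate chain segment",
                        sum(is.na(tab$p))))
    ok <- !is.na(tab$p)
    adj <- p.adjust(tab$p[ok], method = "BH")
    list(table = tab,
         fracSignificant = if (any(ok)) mean(adj < 0.05) else NA_real_,
         nTested = sum(ok))
}

# Geweke z and p for a single chain segment pair
gewekeZ <- function(v, firstFrac = 0.1, lastFrac = 0.5) {
    n <- length(v)
    if (n < 20L)
        stop("chain too short for the Geweke diagnostic")
    first <- v[seq_len(max(2L, floor(firstFrac * n)))]
    last <- v[seq.int(n - max(2L, floor(lastFrac * n)) + 1L, n)]
    if (var(first) == 0 || var(last) == 0) {
        warning("degenerate chain segment; Geweke diagnostic undefined")
        return(list(z = NA_real_, p = NA_real_))
    }
    z <- tryCatch(
        unname(coda::geweke.diag(coda::mcmc(v), frac1 = firstFrac,
                                 frac2 = lastFrac)$z),
        error = function(e) NA_real_)
    if (!is.finite(z)) {
        warning("degenerate chain segment; Geweke diagnostic undefined")
        return(list(z = NA_real_, p = NA_real_))
    }
    list(z = z, p = 2 * pnorm(-abs(z)))
}
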