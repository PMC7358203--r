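#' Posterior probability of differential expression
#'
#' The probability mass of \code{beta} on the same side of zero as its
#' posterior mean: draws with the sign of the mean are counted, draws at
#' exactly zero count towards neither side, and a mean of exactly zero
#' returns 0.5 by convention.
#'
#' @param betaDraws numeric vector of at least 100 posterior draws of
#'   \code{beta}.
#' @return a probability in [0, 1].
#' @export
probDE <- function(betaDraws) {
    if (!length(betaDraws))
        stop("empty draws")
    if (length(betaDraws) < 100L)
        warning("fewer than 100 draws; the probability is noisy")
    m <- mean(betaDraws)
    if (m == 0)
        return(0.5)
    sum(sign(betaDraws) == sign(m)) / length(betaDraws)
}

#' Gene-level posterior probability of differential splicing
#'
#' Under no differential splicing \code{alpha} is uniform, so every entry
#' equals \code{1/T}.  For each isoform the probability is the larger of
#' the posterior mass of \code{alpha[i]} above and below \code{1/T}
#' (draws exactly at \code{1/T} count to neither side); the gene-level
#' probability is the maximum over isoforms.
#'
#' @param alphaDraws draws-by-isoforms matrix of \code{alpha}.
#' @return list with \code{gene} (the maximum) and \code{isoform}
#'   (per-isoform probabilities).
#' @export
probDSGene <- function(alphaDraws) {
    alphaDraws <- as.matrix(alphaDraws)
    T <- ncol(alphaDraws)
    if (T < 2L)
        stop("need at least 2 isoforms")
    null <- 1 / T
    per <- vapply(seq_len(T), function(i) {
        a <- alphaDraws[, i]
        # draws numerically at the null point count to neither side
        max(mean(a > null + 1e-10), mean(a < null - 1e-10))
    }, 0)
    names(per) <- colnames(alphaDraws)
    list(gene = max(per), isoform = per)
}

#' Isoform-level posterior probability of differential splicing
#'
#' The isoform-level null point is the draw-wise dot product
#' \code{c = alpha . p} (which equals \code{1/T} when \code{alpha} is
#' uniform but not in general).  For isoform \code{i} the probability is
#' the larger of the posterior mass of \code{alpha[i]} above and below
#' \code{c}, computed draw by draw.
#'
#' @param alphaDraws,pDraws draws-by-isoforms matrices with matching
#'   dimensions.
#' @return named per-isoform probability vector.
#' @export
probDSIsoform <- function(alphaDraws, pDraws) {
    alphaDraws <- as.matrix(alphaDraws)
    pDraws <- as.matrix(pDraws)
    if (!identical(dim(alphaDraws), dim(pDraws)))
        stop("alpha and p draws must have matching dimensions")
    T <- ncol(alphaDraws)
    if (T < 2L)
        stop("need at least 2 isoforms")
    cc <- rowSums(alphaDraws * pDraws)
    per <- vapply(seq_len(T), function(i) {
        a <- alphaDraws[, i]
        max(mean(a > cc + 1e-10), mean(a < cc - 1e-10))
    }, 0)
    names(per) <- colnames(alphaDraws)
    per
}

#' Posterior fold changes
#'
#' The expression fold change is the posterior mean of \code{beta} (log2
#' units).  The splicing fold change of isoform \code{i} is the Aitchison
#' perturbation of the posterior mean control fractions by the posterior
#' mean of \code{alpha}, divided entrywise by the mean control fractions;
#' both mean vectors are renormalized onto the simplex first.
#'
#' @param geneDraws one gene's draw list (see
#'   \code{\link{geneDraws,PosteriorDraws-method}}).
#' @return list with \code{expr_log2fc} and (for multi-isoform genes)
#'   \code{splicing_fc}.
#' @export
foldChanges <- function(geneDraws) {
    out <- list(expr_log2fc = mean(geneDraws$beta))
    if (!is.null(geneDraws$p)) {
        pBar <- simplexNormalize(colMeans(geneDraws$p))
        aBar <- simplexNormalize(colMeans(geneDraws$alpha))
        out$splicing_fc <- aitchisonPerturb(pBar, aBar) / pBar
    }
    out
}

#' Classify one gene in one comparison
#'
#' \code{DGE} if only the expression probability reaches its threshold,
#' \code{DAST} if only the splicing probability does, \code{DAST/DGE} if
#' both do, \code{static} otherwise.
#'
#' @param probDE,probDS posterior probabilities of differential expression
#'   and (gene-level) differential splicing.  \code{probDS} may be
#'   \code{NA} for single-isoform genes, which can then only be
#'   \code{DGE} or \code{static}.
#' @param threshDE,threshDS probability thresholds in (0.5, 1]; defaults
#'   0.99 for both (gene level).
#' @return one of \code{"DGE"}, \code{"DAST"}, \code{"DAST/DGE"},
#'   \code{"static"}.
#' @export
classifyComparison <- function(probDE, probDS, threshDE = 0.99,
                               threshDS = 0.99) {
    if (threshDE <= 0.5 || threshDE > 1 || threshDS <= 0.5 || threshDS > 1)
        stop("thresholds must lie in (0.5, 1]")
    de <- probDE >= threshDE
    ds <- !is.na(probDS) && probDS >= threshDS
    if (de && ds) "DAST/DGE"
    else if (de) "DGE"
    else if (ds) "DAST"
    else "static"
}

#' Aggregate sub-cohort calls into four mRNA categories
#'
#' For multi-comparison designs (several tissue comparisons, each analysed
#' in several sub-cohorts): a gene counts as differentially expressed in a
#' comparison if it was called DGE or DAST/DGE in at least
#' \code{minCohorts} of its sub-cohorts, and likewise for splicing.  With
#' \code{d} comparisons counted DE and \code{s} counted DS, a gene is
#' splicing-regulated (\code{DAST}) if \code{s >= 2 d} (and \code{s > 0}),
#' expression-regulated (\code{DGE}) if \code{d >= 2 s} (and \code{d > 0}),
#' \code{DAST/DGE} if both occur without either dominating, and
#' \code{static} if neither occurs.
#'
#' @param calls data.frame with columns \code{gene}, \code{comparison},
#'   \code{cohort}, \code{category} (values as produced by
#'   \code{\link{classifyComparison}}).
#' @param minCohorts minimum sub-cohorts for a call to count (default 3).
#' @return data.frame with columns \code{gene}, \code{n_de}, \code{n_ds},
#'   \code{group}.
#' @export
aggregateCohorts <- function(calls, minCohorts = 3L) {
    stopifnot(all(c("gene", "comparison", "cohort", "category") %in%
                  colnames(calls)), minCohorts >= 1L)
    perComp <- do.call(rbind, lapply(
        split(calls, calls[c("gene", "comparison")], drop = TRUE),
        function(d) data.frame(
            gene = d$gene[1L],
            de = sum(d$category %in% c("DGE", "DAST/DGE")) >= minCohorts,
            ds = sum(d$category %in% c("DAST", "DAST/DGE")) >= minCohorts)))
    out <- do.call(rbind, lapply(split(perComp, perComp$gene), function(d) {
        dC <- sum(d$de); sC <- sum(d$ds)
        group <- if (dC == 0L && sC == 0L) "static"
        else if (sC >= 2L * dC && sC > 0L) "DAST"
        else if (dC >= 2L * sC && dC > 0L) "DGE"
        else "DAST/DGE"
        data.frame(gene = d$gene[1L], n_de = dC, n_ds = sC, group = group)
    }))
    rownames(out) <- NULL
    out[order(out$gene), ]
}

#' Turn posterior draws into the results table
#'
#' One gene-level row per gene (the \code{Isoform} column holds the token
#' \code{"Expression"}; \code{log2FC_or_FC} is the posterior mean of
#' \code{beta} and \code{PosteriorProb} the probability of differential
#' expression) plus one row per isoform of multi-isoform genes
#' (\code{log2FC_or_FC} is the splicing fold change and
#' \code{PosteriorProb} the isoform's splicing probability).  The
#' \code{Category} column carries the gene's classification on every row.
#'
#' @param pd a \linkS4class{PosteriorDraws}.
#' @param threshDE,threshDS classification thresholds (defaults 0.99).
#' @param isoformLevel if \code{TRUE}, isoform probabilities use the
#'   isoform-level null point \code{alpha . p}
#'   (\code{\link{probDSIsoform}}) and the gene-level splicing call is
#'   their maximum; otherwise the gene-level null \code{1/T} is used
#'   (\code{\link{probDSGene}}).
#' @return a \linkS4class{DuetResults}.
#' @export
posteriorCalls <- function(pd, threshDE = 0.99, threshDS = 0.99,
                           isoformLevel = FALSE) {
    stopifnot(is(pd, "PosteriorDraws"))
    rows <- vector("list", length(pd@draws))
    for (k in seq_along(pd@draws)) {
        g <- names(pd@draws)[k]
        d <- pd@draws[[k]]
        pDE <- probDE(d$beta)
        fc <- foldChanges(d)
        if (is.null(d$p)) {
            pDS <- NA_real_
            iso <- NULL
        } else if (isoformLevel) {
            iso <- probDSIsoform(d$alpha, d$p)
            pDS <- max(iso)
        } else {
            dsg <- probDSGene(d$alpha)
            iso <- dsg$isoform
            pDS <- dsg$gene
        }
        cat_ <- classifyComparison(pDE, pDS, threshDE, threshDS)
        geneRow <- data.frame(Gene = g, Isoform = "Expression",
                              log2FC_or_FC = fc$expr_log2fc,
                              PosteriorProb = pDE, Category = cat_)
        isoRows <- if (is.null(iso)) NULL else
            data.frame(Gene = g, Isoform = names(iso),
                       log2FC_or_FC = unname(fc$splicing_fc),
                       PosteriorProb = unname(iso), Category = cat_)
        rows[[k]] <- rbind(geneRow, isoRows)
    }
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    new("DuetResults", table = tab, draws = pd,
        settings = list(threshDE = threshDE, threshDS = threshDS,
                        isoformLevel = isoformLevel),
        geweke = list())
}
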