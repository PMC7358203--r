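#' Precision-recall curve container
#'
#' @slot threshold statistic cutoffs (may be empty for derived curves).
#' @slot precision,recall operating points, aligned with
#'   \code{threshold} where present.
#' @slot auprc trapezoidal area under the recall-sorted curve.
#' @export
setClass("PRCurve",
    representation(threshold = "numeric", precision = "numeric",
                   recall = "numeric", auprc = "numeric"))

setValidity("PRCurve", function(object) {
    pr <- c(object@precision, object@recall)
    if (any(pr[!is.na(pr)] < 0 | pr[!is.na(pr)] > 1))
        return("precision and recall must lie in [0, 1]")
    if (!is.na(object@auprc) && (object@auprc < 0 || object@auprc > 1))
        return("AUPRC must lie in [0, 1]")
    TRUE
})

setMethod("show", "PRCurve", function(object) {
    cat(sprintf("PRCurve: %d points, AUPRC = %.4f\n",
                length(object@recall), object@auprc))
})

#' @rdname PRCurve-class
#' @param x a \code{PRCurve}.
#' @return \code{auprc} returns the area under the curve.
#' @export
auprc <- function(x) {
    stopifnot(is(x, "PRCurve"))
    x@auprc
}

# trapezoid over the recall-sorted curve.  Several thresholds can share a
# recall level (extra calls that add only false positives); only the best
# (maximum-precision) operating point per recall lies on the PR envelope.
# Anchored at recall 0 with the envelope precision of the lowest recall.
trapezoidAuprc <- function(recall, precision) {
    ok <- !is.na(precision) & !is.na(recall)
    r <- recall[ok]; p <- precision[ok]
    if (!length(r))
        return(NA_real_)
    env <- tapply(p, r, max)
    r <- as.numeric(names(env)); p <- as.numeric(env)
    o <- order(r)
    r <- r[o]; p <- p[o]
    if (r[1L] > 0) {
        r <- c(0, r); p <- c(p[1L], p)
    }
    sum(diff(r) * (utils::head(p, -1L) + utils::tail(p, -1L)) / 2)
}

#' Per-sample isoform proportions against the rest of the gene
#'
#' For every isoform of a multi-isoform gene, the count divided by the sum
#' of the counts of the gene's \emph{other} isoforms in the same sample.
#' Single-isoform genes are excluded; a zero complement (all other
#' isoforms at zero) yields \code{NA} for that cell.
#'
#' @param x an \linkS4class{IsoformExperiment}.
#' @return numeric matrix (isoforms of multi-isoform genes by samples).
#' @export
isoformProportions <- function(x) {
    stopifnot(is(x, "IsoformExperiment"))
    cts <- SummarizedExperiment::assay(x, "counts")
    g <- geneIds(x)
    multi <- g %in% names(which(table(g) >= 2L))
    cts <- cts[multi, , drop = FALSE]
    g <- g[multi]
    geneSum <- rowsum(cts, g, reorder = FALSE)[g, , drop = FALSE]
    other <- geneSum - cts
    props <- cts / other
    props[other == 0] <- NA_real_
    props
}

#' Per-row two-sample t statistics
#'
#' Welch (default) or pooled-variance t statistics of each row between the
#' two conditions, tolerating \code{NA} cells (a row needs at least two
#' usable values per group).  Rows with zero variance in both groups are
#' returned as \code{NA}.
#'
#' @param mat numeric matrix (rows = features, columns = samples).
#' @param condition condition factor aligned with the columns.
#' @param welch use the unequal-variance form (default TRUE).
#' @return list with \code{statistic} and \code{p.value} per row.
#' @export
rowTStatistics <- function(mat, condition, welch = TRUE) {
    ctrl <- condition == "control"
    g1 <- mat[, ctrl, drop = FALSE]
    g2 <- mat[, !ctrl, drop = FALSE]
    n1 <- rowSums(!is.na(g1)); n2 <- rowSums(!is.na(g2))
    m1 <- rowMeans(g1, na.rm = TRUE); m2 <- rowMeans(g2, na.rm = TRUE)
    v1 <- apply(g1, 1L, var, na.rm = TRUE)
    v2 <- apply(g2, 1L, var, na.rm = TRUE)
    bad <- n1 < 2L | n2 < 2L
    if (welch) {
        se2 <- v1 / n1 + v2 / n2
        stat <- (m2 - m1) / sqrt(se2)
        df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    } else {
        sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
        stat <- (m2 - m1) / sqrt(sp2 * (1 / n1 + 1 / n2))
        df <- n1 + n2 - 2
    }
    stat[bad | !is.finite(stat)] <- NA_real_
    p <- 2 * stats::pt(-abs(stat), df)
    list(statistic = stat, p.value = p)
}

#' Oracle t-statistic splicing baseline (OSTP)
#'
#' An upper bound on the performance of t-statistic-based splicing calls:
#' isoform proportions (count over the sum of the gene's other isoforms)
#' are compared between conditions with a two-sample t statistic, and for
#' every achievable false-positive count the |t| cutoff that maximizes the
#' number of detected true positives is chosen.  True positives are the
#' truly differentially spliced isoforms with a within-gene fraction fold
#' change of 2 or more (in either direction).  Requires ground truth, so
#' it is usable only on simulated data.
#'
#' @param x an \linkS4class{IsoformExperiment} (simulated counts).
#' @param truth the matching \linkS4class{SimulationTruth}.
#' @param welch use the Welch t statistic (default TRUE).
#' @return a \linkS4class{PRCurve} (thresholds are |t| cutoffs).
#' @export
ostpCurve <- function(x, truth, welch = TRUE) {
    stopifnot(is(truth, "SimulationTruth"))
    props <- isoformProportions(x)
    tt <- rowTStatistics(props, conditionLabels(x), welch = welch)
    stat <- abs(tt$statistic)
    flags <- truthSplicingFlags(truth)[rownames(props)]
    usable <- !is.na(stat)
    if (any(!usable))
        warning(sprintf("%d isoform(s) with undefined t statistic skipped",
                        sum(!usable)))
    stat <- stat[usable]; flags <- flags[usable]
    P <- sum(truthSplicingFlags(truth))
    if (P == 0L)
        stop("no true positives in truth")
    op <- ostpOperatingPoints(stat, flags)
    prec <- op$tp / (op$tp + op$fp)
    rec <- op$tp / P
    new("PRCurve", threshold = op$threshold, precision = prec,
        recall = rec, auprc = trapezoidAuprc(rec, prec))
}

# best (maximum-TP) |t| cutoff for every achievable false-positive count;
# only tie-group boundaries are valid cutpoints
ostpOperatingPoints <- function(stat, flags) {
    o <- order(stat, decreasing = TRUE)
    ss <- stat[o]
    tp <- cumsum(flags[o])
    fp <- cumsum(!flags[o])
    n <- length(ss)
    boundary <- c(ss[-n] != ss[-1], TRUE)
    tp <- tp[boundary]; fp <- fp[boundary]; thr <- ss[boundary]
    keep <- !duplicated(fp, fromLast = TRUE)
    list(tp = tp[keep], fp = fp[keep], threshold = thr[keep])
}

# truly differentially spliced isoforms with fold change >= 2 either way
truthSplicingFlags <- function(truth) {
    iso <- truthIsoforms(truth)
    fc <- pmax(iso$splicing_fc, 1 / iso$splicing_fc)
    setNames(iso$is_ds_isoform & fc >= 2 - 1e-9, iso$isoform)
}

#' Precision-recall curve over a statistic grid
#'
#' Sweeps a call threshold over a regular grid on [0, 1] (default step
#' 1e-4); at each threshold items with \code{score >= threshold} are
#' called, giving precision TP/(TP+FP) and recall TP/P.  The area under
#' the curve is the trapezoid over the recall-sorted points.
#'
#' @param scores per-item statistic in [0, 1] (e.g. posterior
#'   probabilities).
#' @param truthFlags logical ground-truth positives, aligned with
#'   \code{scores}.
#' @param gridStep grid spacing (default 1e-4).
#' @return a \linkS4class{PRCurve}.
#' @export
prCurve <- function(scores, truthFlags, gridStep = 1e-4) {
    stopifnot(length(scores) == length(truthFlags))
    if (any(scores < 0 | scores > 1, na.rm = TRUE))
        stop("scores must lie in [0, 1]")
    ok <- !is.na(scores)
    scores <- scores[ok]; truthFlags <- as.logical(truthFlags)[ok]
    P <- sum(truthFlags)
    if (P == 0L)
        stop("no true positives in truth")
    thr <- seq(0, 1, by = gridStep)
    sPos <- sort(scores[truthFlags])
    sNeg <- sort(scores[!truthFlags])
    # counts with score >= threshold
    tp <- length(sPos) - findInterval(thr - gridStep * 1e-6, sPos)
    fp <- length(sNeg) - findInterval(thr - gridStep * 1e-6, sNeg)
    prec <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
    rec <- tp / P
    new("PRCurve", threshold = thr, precision = prec, recall = rec,
        auprc = trapezoidAuprc(rec, prec))
}

#' Mean of several precision-recall curves
#'
#' Each curve's precision is smoothed over recall with \code{lowess};
#' precision at a recall grid point that a curve never reaches is imputed
#' by carrying the value at the nearest lower recall.  The smoothed values
#' are then averaged pointwise across curves.
#'
#' @param curves list of \linkS4class{PRCurve} objects (at least 2).
#' @param recallGrid common recall grid (default \code{seq(0, 1, 0.01)}).
#' @param span lowess span (default 2/3).
#' @return a \linkS4class{PRCurve} on \code{recallGrid}.
#' @export
meanPRCurve <- function(curves, recallGrid = seq(0, 1, by = 0.01),
                        span = 2 / 3) {
    stopifnot(length(curves) >= 2L,
              all(vapply(curves, is, TRUE, "PRCurve")))
    sm <- vapply(curves, function(cv) {
        ok <- !is.na(cv@precision)
        r <- cv@recall[ok]; p <- cv@precision[ok]
        fit <- lowess(r, p, f = span)
        # carry precision from the nearest lower recall
        approx(fit$x, fit$y, xout = recallGrid, method = "constant",
               f = 0, rule = 2, ties = mean)$y
    }, numeric(length(recallGrid)))
    meanP <- pmin(pmax(rowMeans(sm), 0), 1)
    new("PRCurve", threshold = numeric(), precision = meanP,
        recall = recallGrid, auprc = trapezoidAuprc(recallGrid, meanP))
}

#' Scores for the expression t-test baseline
#'
#' Per-gene two-sample t-test on gene-level log2-cpm, returned as
#' \code{1 - p} so larger means more significant and the score lies in
#' [0, 1] for use with \code{\link{prCurve}}.
#'
#' @param x an \linkS4class{IsoformExperiment} (isoform counts; summed to
#'   gene level internally).
#' @param welch use the Welch t statistic (default TRUE).
#' @return named per-gene score vector.
#' @export
deTTestScores <- function(x, welch = TRUE) {
    gx <- cpmLogTransform(geneLevelSum(x), librarySizes = librarySizes(x))
    tt <- rowTStatistics(logCpm(gx), conditionLabels(gx), welch = welch)
    setNames(1 - tt$p.value, rownames(gx))
}
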