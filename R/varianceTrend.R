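#' Fit a mean-variance trend on the log2-cpm scale
#'
#' For every row of the log2-cpm matrix a two-group-means linear model
#' (intercept plus condition indicator) is fitted across samples; the
#' residual standard deviation \code{s} and the row mean log2-cpm \code{m}
#' give one point \code{(m, sqrt(s))}.  A LOWESS curve through these points
#' is the trend.  The square-root-of-sd scale follows the usual
#' mean-variance modelling of log-cpm data; per-observation variances are
#' recovered as the fourth power of the trend value
#' (\code{\link{observationVariances}}).
#'
#' The same function serves the gene-level matrix (from
#' \code{\link{geneLevelSum}}) and the isoform-level matrix; the two trends
#' are fitted independently.
#'
#' @param x an \linkS4class{IsoformExperiment} carrying a \code{"logcpm"}
#'   assay (see \code{\link{cpmLogTransform}}).
#' @param span LOWESS smoother span (default 0.5).
#' @param iterations number of robustifying LOWESS iterations (default 3).
#' @return a \linkS4class{VarianceTrend}.
#' @export
fitVarianceTrend <- function(x, span = 0.5, iterations = 3L) {
    stopifnot(is(x, "IsoformExperiment"))
    lcpm <- logCpm(x)
    cond <- conditionLabels(x)
    if (nlevels(droplevels(cond)) < 2L)
        stop("both conditions must be present")
    if (nrow(lcpm) < 10L)
        warning("fewer than 10 rows; the variance trend may be unstable")
    st <- rowGroupStats(lcpm, cond)
    if (all(st$sd == 0))
        stop("degenerate variance structure: all residual sds are zero")
    m <- st$mean
    y <- sqrt(st$sd)
    keep <- is.finite(m) & is.finite(y)
    fit <- lowess(m[keep], y[keep], f = span, iter = iterations)
    # collapse duplicated abscissae and floor at a small positive value so
    # the readback variance stays > 0
    ux <- tapply(fit$y, fit$x, mean)
    xs <- as.numeric(names(ux))
    ys <- pmax(as.numeric(ux), 1e-4)
    new("VarianceTrend", x = xs, y = ys,
        supportRange = range(xs), span = span,
        iterations = as.integer(iterations))
}

# residual sd of the two-group-means model and pooled row mean, vectorized
rowGroupStats <- function(lcpm, cond) {
    ctrl <- cond == "control"
    n1 <- sum(ctrl); n2 <- sum(!ctrl)
    m1 <- rowMeans(lcpm[, ctrl, drop = FALSE])
    m2 <- rowMeans(lcpm[, !ctrl, drop = FALSE])
    rss <- rowSums((lcpm[, ctrl, drop = FALSE] - m1)^2) +
           rowSums((lcpm[, !ctrl, drop = FALSE] - m2)^2)
    df <- n1 + n2 - 2L
    list(mean = rowMeans(lcpm), meanControl = m1, meanCase = m2,
         sd = sqrt(rss / df))
}

#' Evaluate a variance trend
#'
#' \code{trendValue} interpolates the fitted curve at \code{at} (clamped to
#' the fitted support) and returns the predicted square root of the
#' residual standard deviation.
#'
#' @param trend a \linkS4class{VarianceTrend}.
#' @param at numeric vector of mean log2-cpm values.
#' @return positive numeric vector, same length as \code{at}.
#' @export
trendValue <- function(trend, at) {
    stopifnot(is(trend, "VarianceTrend"))
    if (length(trend@x) == 1L)
        return(rep(trend@y, length(at)))
    approx(trend@x, trend@y, xout = at, rule = 2)$y
}

#' Per-observation variances from the trend
#'
#' Every observation of a row is assigned the variance implied by the
#' fitted value of the row's two-group model, i.e. the condition-specific
#' mean log2-cpm: the trend (predicted sqrt of sd) is evaluated there and
#' raised to the fourth power.  Samples of the same condition therefore
#' share a variance within a row.
#'
#' @param trend a \linkS4class{VarianceTrend} fitted on compatible data.
#' @param x the \linkS4class{IsoformExperiment} (with \code{"logcpm"}
#'   assay) to assign variances for.
#' @return a matrix of positive variances, same dimensions as the log2-cpm
#'   assay.
#' @export
observationVariances <- function(trend, x) {
    stopifnot(is(trend, "VarianceTrend"), is(x, "IsoformExperiment"))
    lcpm <- logCpm(x)
    cond <- conditionLabels(x)
    st <- rowGroupStats(lcpm, cond)
    v1 <- trendValue(trend, st$meanControl)^4
    v2 <- trendValue(trend, st$meanCase)^4
    out <- matrix(NA_real_, nrow(lcpm), ncol(lcpm),
                  dimnames = dimnames(lcpm))
    out[, cond == "control"] <- v1
    out[, cond == "case"] <- v2
    out
}
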