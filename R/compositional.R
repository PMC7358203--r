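#' Simplex utilities and the Aitchison perturbation
#'
#' Isoform usage of a gene with \code{T} isoforms lives on the open simplex:
#' \code{T} strictly positive fractions summing to 1.  The Aitchison
#' perturbation is the group operation on the simplex: the elementwise
#' product of two composition vectors, renormalized to sum 1.  A gene's case
#' fractions are the control fractions perturbed by \code{alpha}; the
#' uniform vector \code{(1/T, ..., 1/T)} is the identity element, so
#' \code{alpha} uniform means no change in isoform usage.
#'
#' @param p,alpha numeric vectors of equal length \code{T >= 2} on the
#'   simplex.  Entries at or below zero (as can arise from degenerate
#'   numerical summaries) are floored at 1e-12 before renormalization.
#' @return \code{aitchisonPerturb} returns the perturbed composition
#'   \code{p * alpha / sum(p * alpha)}.
#' @examples
#' aitchisonPerturb(c(0.4, 0.6), c(0.6, 0.4))   # (0.5, 0.5)
#' aitchisonPerturb(c(0.2, 0.3, 0.5), uniformAlpha(3))  # identity
#' @export
aitchisonPerturb <- function(p, alpha) {
    p <- validateSimplex(p, "p")
    alpha <- validateSimplex(alpha, "alpha")
    if (length(p) != length(alpha))
        stop("p and alpha must have equal length")
    w <- p * alpha
    w / sum(w)
}

#' @rdname aitchisonPerturb
#' @param T integer number of isoforms, at least 2.
#' @return \code{uniformAlpha} returns the identity element
#'   \code{rep(1/T, T)}.
#' @export
uniformAlpha <- function(T) {
    T <- as.integer(T)
    if (is.na(T) || T < 2L)
        stop("T must be an integer >= 2")
    rep(1 / T, T)
}

#' @rdname aitchisonPerturb
#' @details \code{aitchisonInverse} returns the inverse element of
#'   \code{alpha}, i.e. the normalized entrywise reciprocal, so that
#'   perturbing by \code{alpha} and then by its inverse is the identity.
#' @export
aitchisonInverse <- function(alpha) {
    alpha <- validateSimplex(alpha, "alpha")
    inv <- 1 / alpha
    inv / sum(inv)
}

#' @rdname aitchisonPerturb
#' @param x a numeric vector of positive weights.
#' @return \code{simplexNormalize} returns \code{x} floored at 1e-12 and
#'   scaled to sum 1.
#' @export
simplexNormalize <- function(x) {
    if (length(x) < 2L)
        stop("a composition needs at least 2 parts")
    if (any(!is.finite(x)))
        stop("composition entries must be finite")
    x <- pmax(x, 1e-12)
    x / sum(x)
}

# shared validation: length, positivity (with 1e-12 flooring), unit sum
validateSimplex <- function(x, what) {
    if (length(x) < 2L)
        stop(sprintf("'%s' must have at least 2 entries", what))
    if (any(!is.finite(x)) || any(x < 0))
        stop(sprintf("'%s' must have finite non-negative entries", what))
    x <- pmax(x, 1e-12)
    s <- sum(x)
    if (abs(s - 1) > 1e-6)
        stop(sprintf("'%s' must sum to 1 (got %.8f)", what, s))
    x / s
}
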