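# independent sort-based PR computation used as the oracle for the
# grid-based implementation
bruteForcePR <- function(scores, flags) {
    cuts <- sort(unique(scores))
    pts <- t(vapply(cuts, function(thr) {
        called <- scores >= thr
        c(prec = sum(called & flags) / sum(called),
          rec = sum(called & flags) / sum(flags))
    }, c(prec = 0, rec = 0)))
    env <- tapply(pts[, "prec"], pts[, "rec"], max)
    r <- as.numeric(names(env)); p <- as.numeric(env)
    o <- order(r); r <- r[o]; p <- p[o]
    if (r[1] > 0) { r <- c(0, r); p <- c(p[1], p) }
    sum(diff(r) * (head(p, -1) + tail(p, -1)) / 2)
}
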