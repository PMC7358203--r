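#' Read an isoform count matrix from TSV
#'
#' The expected format is tab-delimited with a header row: column 1 the gene
#' id, column 2 the isoform id, columns 3..N one per sample with the control
#' samples first.  Counts may be fractional (RSEM-style expected counts) and
#' are kept as given.
#'
#' @param path path to the TSV file.
#' @param nControl number of control samples; the first \code{nControl}
#'   sample columns are labelled \code{control}, the rest \code{case}.
#'   Both groups must contain at least 2 samples.
#' @return an \linkS4class{IsoformExperiment}.
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c("Gene\tIsoform\ts1\ts2\ts3\ts4",
#'              "g1\ti1\t10\t12\t30\t28",
#'              "g1\ti2\t20\t18\t10\t12",
#'              "g2\ti3\t5\t6\t5\t7"), tsv)
#' readIsoformCounts(tsv, nControl = 2)
#' @export
readIsoformCounts <- function(path, nControl) {
    if (!file.exists(path))
        stop(sprintf("counts file not found: '%s'", path))
    tab <- read.delim(path, header = TRUE, sep = "\t",
                      check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 6L)
        stop("need gene and isoform columns plus at least 4 sample columns")
    nSamples <- ncol(tab) - 2L
    if (nControl < 2L || nControl > nSamples - 2L)
        stop("nControl must be >= 2 and leave at least 2 case samples")
    isoforms <- as.character(tab[[2L]])
    if (anyDuplicated(isoforms))
        stop(sprintf("duplicated isoform id '%s'",
                     isoforms[duplicated(isoforms)][1L]))
    cts <- as.matrix(tab[, -(1:2), drop = FALSE])
    if (!is.numeric(cts) || anyNA(cts)) {
        bad <- which(is.na(suppressWarnings(
            matrix(as.numeric(cts), nrow(cts)))), arr.ind = TRUE)
        if (nrow(bad))
            stop(sprintf("malformed count at isoform '%s', sample '%s'",
                         isoforms[bad[1L, 1L]], colnames(cts)[bad[1L, 2L]]))
        stop("count columns must be numeric")
    }
    if (any(cts < 0)) {
        bad <- which(cts < 0, arr.ind = TRUE)[1L, ]
        stop(sprintf("negative count at isoform '%s', sample '%s'",
                     isoforms[bad[1L]], colnames(cts)[bad[2L]]))
    }
    rownames(cts) <- isoforms
    cond <- rep(c("control", "case"), c(nControl, nSamples - nControl))
    IsoformExperiment(cts, geneIds = as.character(tab[[1L]]),
                      condition = cond)
}

#' Filter low-count isoforms
#'
#' Retains only isoforms with a count of at least \code{minCount} in every
#' sample.  Genes left with no isoforms are dropped; genes reduced to one
#' isoform are retained and analysed for expression only (splicing is
#' undefined for a single isoform).
#'
#' @param x an \linkS4class{IsoformExperiment}.
#' @param minCount minimum per-sample count (default 1).
#' @return the filtered \linkS4class{IsoformExperiment}.
#' @export
filterLowCounts <- function(x, minCount = 1) {
    stopifnot(is(x, "IsoformExperiment"), minCount >= 0)
    cts <- SummarizedExperiment::assay(x, "counts")
    keep <- rowSums(cts >= minCount) == ncol(cts)
    if (!any(keep))
        stop("no isoforms pass filter")
    x[keep, ]
}

#' Log2 counts-per-million transform
#'
#' Computes \code{log2(counts / library_size * 1e6 + 0.5)} per cell, where
#' the library size is the per-sample total over all isoforms, and stores it
#' as the \code{"logcpm"} assay together with the library sizes in
#' \code{colData$lib_size}.
#'
#' @param x an \linkS4class{IsoformExperiment}.
#' @param librarySizes optional externally supplied library sizes (used to
#'   transform a gene-level matrix on the same scale as the isoform matrix);
#'   defaults to the column sums of \code{x}.
#' @return \code{x} with the extra assay.
#' @export
cpmLogTransform <- function(x, librarySizes = NULL) {
    stopifnot(is(x, "IsoformExperiment"))
    cts <- SummarizedExperiment::assay(x, "counts")
    ls <- if (is.null(librarySizes)) colSums(cts) else librarySizes
    if (any(ls <= 0))
        stop(sprintf("zero library size in sample '%s'",
                     colnames(cts)[which(ls <= 0)[1L]]))
    lcpm <- log2(sweep(cts, 2L, ls, "/") * 1e6 + 0.5)
    SummarizedExperiment::assay(x, "logcpm") <- lcpm
    x$lib_size <- unname(ls)
    x
}

#' Sum isoform counts to gene level
#'
#' Collapses the count matrix to one row per gene by summing the counts of
#' each gene's isoforms within every sample.  The returned object uses the
#' gene ids as both isoform and gene identifiers.
#'
#' @param x an \linkS4class{IsoformExperiment}.
#' @return a gene-level \linkS4class{IsoformExperiment}.
#' @export
geneLevelSum <- function(x) {
    stopifnot(is(x, "IsoformExperiment"))
    cts <- SummarizedExperiment::assay(x, "counts")
    g <- factor(geneIds(x), levels = unique(geneIds(x)))
    gcts <- rowsum(cts, g, reorder = FALSE)
    IsoformExperiment(gcts, geneIds = rownames(gcts),
                      condition = conditionLabels(x))
}
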