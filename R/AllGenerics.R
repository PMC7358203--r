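#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname accessors
#' @export
setGeneric("isoformIds", function(x) standardGeneric("isoformIds"))

#' @rdname accessors
#' @export
setGeneric("conditionLabels", function(x) standardGeneric("conditionLabels"))

#' @rdname accessors
#' @export
setGeneric("librarySizes", function(x) standardGeneric("librarySizes"))

#' @rdname accessors
#' @export
setGeneric("logCpm", function(x) standardGeneric("logCpm"))

#' @rdname PosteriorDraws-accessors
#' @export
setGeneric("nDraws", function(x) standardGeneric("nDraws"))

#' @rdname PosteriorDraws-accessors
#' @export
setGeneric("geneDraws", function(x, gene) standardGeneric("geneDraws"))

#' @rdname DuetResults-accessors
#' @export
setGeneric("resultsTable", function(x) standardGeneric("resultsTable"))

#' @rdname SimulationTruth-accessors
#' @export
setGeneric("truthGenes", function(x) standardGeneric("truthGenes"))

#' @rdname SimulationTruth-accessors
#' @export
setGeneric("truthIsoforms", function(x) standardGeneric("truthIsoforms"))

#' Accessors for IsoformExperiment
#'
#' \code{geneIds} returns the per-isoform gene identifiers;
#' \code{isoformIds} the isoform identifiers; \code{conditionLabels} the
#' condition factor; \code{librarySizes} the per-sample total counts;
#' \code{logCpm} the log2 counts-per-million assay (available after
#' \code{\link{cpmLogTransform}}).
#'
#' @param x an \linkS4class{IsoformExperiment}.
#' @return see the individual descriptions.
#' @name accessors
NULL

#' Accessors for PosteriorDraws
#'
#' \code{nDraws} returns the number of post-warmup draws; \code{geneDraws}
#' the draw list (\code{beta0}, \code{beta}, and for multi-isoform genes
#' \code{p} and \code{alpha}) for one gene.
#'
#' @param x a \linkS4class{PosteriorDraws}.
#' @param gene a gene identifier.
#' @name PosteriorDraws-accessors
NULL

#' Accessors for DuetResults
#'
#' @param x a \linkS4class{DuetResults}.
#' @return \code{resultsTable} returns the results data.frame.
#' @name DuetResults-accessors
NULL

#' Accessors for SimulationTruth
#'
#' @param x a \linkS4class{SimulationTruth}.
#' @return \code{truthGenes} and \code{truthIsoforms} return the per-gene
#'   and per-isoform ground-truth data.frames.
#' @name SimulationTruth-accessors
NULL

#' @rdname accessors
#' @export
setMethod("geneIds", "IsoformExperiment", function(x)
    as.character(SummarizedExperiment::rowData(x)$gene_id))

#' @rdname accessors
#' @export
setMethod("isoformIds", "IsoformExperiment", function(x) rownames(x))

#' @rdname accessors
#' @export
setMethod("conditionLabels", "IsoformExperiment", function(x) x$condition)

#' @rdname accessors
#' @export
setMethod("librarySizes", "IsoformExperiment", function(x)
    colSums(SummarizedExperiment::assay(x, "counts")))

#' @rdname accessors
#' @export
setMethod("logCpm", "IsoformExperiment", function(x) {
    if (!"logcpm" %in% SummarizedExperiment::assayNames(x))
        stop("no 'logcpm' assay; run cpmLogTransform() first")
    SummarizedExperiment::assay(x, "logcpm")
})

#' @rdname PosteriorDraws-accessors
#' @export
setMethod("nDraws", "PosteriorDraws", function(x) x@steps - x@warmup)

#' @rdname PosteriorDraws-accessors
#' @export
setMethod("geneDraws", "PosteriorDraws", function(x, gene) {
    if (!gene %in% names(x@draws))
        stop(sprintf("no draws for gene '%s'", gene))
    x@draws[[gene]]
})

#' @rdname DuetResults-accessors
#' @export
setMethod("resultsTable", "DuetResults", function(x) x@table)

#' @rdname SimulationTruth-accessors
#' @export
setMethod("truthGenes", "SimulationTruth", function(x) x@genes)

#' @rdname SimulationTruth-accessors
#' @export
setMethod("truthIsoforms", "SimulationTruth", function(x) x@isoforms)
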