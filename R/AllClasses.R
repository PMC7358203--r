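#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<-
#'   assayNames rowData colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats approx lowess median p.adjust pnorm quantile rgamma
#'   rlnorm rnbinom runif rmultinom sd setNames t.test var
#' @importFrom utils read.delim write.table
#' @importFrom Rcpp sourceCpp
#' @useDynLib duet, .registration = TRUE
NULL

#' IsoformExperiment: isoform-level counts for a two-condition design
#'
#' A thin \linkS4class{SummarizedExperiment} subclass holding an
#' isoform-by-sample count matrix (assay \code{"counts"}), the gene each
#' isoform belongs to (\code{rowData} column \code{gene_id}) and a
#' two-level condition factor (\code{colData} column \code{condition},
#' levels \code{control}, \code{case}).  After
#' \code{\link{cpmLogTransform}} the object additionally carries a
#' \code{"logcpm"} assay and per-sample library sizes in
#' \code{colData$lib_size}.
#'
#' @slot .  inherits all slots from \code{SummarizedExperiment}.
#' @seealso \code{\link{readIsoformCounts}}, \code{\link{filterLowCounts}},
#'   \code{\link{geneLevelSum}}
#' @export
setClass("IsoformExperiment", contains = "SummarizedExperiment")

setValidity("IsoformExperiment", function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        cts <- SummarizedExperiment::assay(object, "counts")
        if (any(!is.finite(cts)))
            msg <- c(msg, "counts must be finite")
        else if (any(cts < 0)) {
            bad <- which(cts < 0, arr.ind = TRUE)[1L, ]
            msg <- c(msg, sprintf("negative count at isoform '%s', sample '%s'",
                                  rownames(object)[bad[1L]],
                                  colnames(object)[bad[2L]]))
        }
    }
    if (is.null(rownames(object)))
        msg <- c(msg, "isoform identifiers (rownames) are required")
    else if (anyDuplicated(rownames(object)))
        msg <- c(msg, sprintf("duplicated isoform id '%s'",
                              rownames(object)[duplicated(rownames(object))][1L]))
    if (!"gene_id" %in% colnames(SummarizedExperiment::rowData(object)))
        msg <- c(msg, "rowData column 'gene_id' is required")
    cd <- SummarizedExperiment::colData(object)
    if (!"condition" %in% colnames(cd))
        msg <- c(msg, "colData column 'condition' is required")
    else {
        cond <- cd$condition
        if (!is.factor(cond) || !identical(levels(cond), c("control", "case")))
            msg <- c(msg, "condition must be a factor with levels control, case")
        else if (any(table(cond) < 2L))
            msg <- c(msg, "both conditions need at least 2 samples")
    }
    if (length(msg)) msg else TRUE
})

#' Construct an IsoformExperiment
#'
#' @param counts numeric matrix, isoforms in rows, samples in columns.
#'   Fractional values are allowed (e.g. RSEM expected counts).
#' @param geneIds character vector, one gene id per isoform row.
#' @param condition character/factor of \code{"control"}/\code{"case"}
#'   per sample, or a logical where \code{TRUE} marks controls.
#' @param isoformIds isoform identifiers; defaults to \code{rownames(counts)}.
#'
#' @return a validated \linkS4class{IsoformExperiment}.
#' @examples
#' cts <- matrix(rpois(24, 50), nrow = 6,
#'               dimnames = list(paste0("iso", 1:6), paste0("s", 1:4)))
#' ie <- IsoformExperiment(cts, geneIds = rep(c("g1", "g2"), each = 3),
#'                         condition = c("control", "control", "case", "case"))
#' ie
#' @export
IsoformExperiment <- function(counts, geneIds, condition,
                              isoformIds = rownames(counts)) {
    counts <- as.matrix(counts)
    if (is.null(isoformIds))
        stop("isoform identifiers are required")
    rownames(counts) <- isoformIds
    if (is.null(colnames(counts)))
        colnames(counts) <- paste0("sample", seq_len(ncol(counts)))
    if (length(geneIds) != nrow(counts))
        stop("geneIds must have one entry per isoform row")
    cond <- factor(as.character(condition), levels = c("control", "case"))
    if (anyNA(cond))
        stop("condition labels must be 'control' or 'case'")
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts),
        rowData = S4Vectors::DataFrame(gene_id = as.character(geneIds),
                                       row.names = rownames(counts)),
        colData = S4Vectors::DataFrame(condition = cond,
                                       row.names = colnames(counts)))
    new("IsoformExperiment", se)
}

#' Mean-variance trend
#'
#' A LOWESS curve relating mean log2-cpm to the square root of the residual
#' standard deviation of a per-row two-group linear model.  Evaluation
#' outside the fitted support is clamped to the boundary values, and the
#' per-observation variance is the fourth power of the predicted value.
#'
#' @slot x,y coordinates of the fitted (sorted, deduplicated) curve.
#' @slot supportRange range of mean log2-cpm used in fitting.
#' @slot span,iterations LOWESS smoothing parameters used.
#' @seealso \code{\link{fitVarianceTrend}}, \code{\link{observationVariances}}
#' @export
setClass("VarianceTrend",
    representation(x = "numeric", y = "numeric", supportRange = "numeric",
                   span = "numeric", iterations = "integer"))

setValidity("VarianceTrend", function(object) {
    if (length(object@x) != length(object@y))
        return("x and y must have equal length")
    if (any(object@y <= 0))
        return("trend values must be positive on the support")
    TRUE
})

#' Posterior draws for all genes
#'
#' Post-warmup MCMC draws of the per-gene parameters: \code{beta0} (control
#' mean log2-cpm), \code{beta} (case minus control shift, log2 units) and,
#' for multi-isoform genes, the control fraction vector \code{p} and the
#' perturbation vector \code{alpha} (rows of the matrices are draws).
#'
#' @slot draws named list, one element per gene with components
#'   \code{beta0}, \code{beta} and (if the gene has two or more isoforms)
#'   \code{p}, \code{alpha}, \code{isoform_ids}.
#' @slot warmup,steps,seed sampler settings.
#' @slot diagnostics per-gene data.frame with acceptance rates.
#' @export
setClass("PosteriorDraws",
    representation(draws = "list", warmup = "integer", steps = "integer",
                   seed = "integer", diagnostics = "data.frame"))

setValidity("PosteriorDraws", function(object) {
    if (object@steps <= object@warmup)
        return("steps must exceed warmup")
    TRUE
})

#' Results of a joint expression/splicing analysis
#'
#' @slot table results data.frame with columns \code{Gene}, \code{Isoform}
#'   (the token \code{"Expression"} on gene-level rows),
#'   \code{log2FC_or_FC}, \code{PosteriorProb} and \code{Category}.
#' @slot draws the \linkS4class{PosteriorDraws} the table was derived from.
#' @slot settings list of thresholds and sampler settings.
#' @slot geweke Geweke convergence summary (see
#'   \code{\link{gewekeDiagnostic}}), or an empty list.
#' @export
setClass("DuetResults",
    representation(table = "data.frame", draws = "PosteriorDraws",
                   settings = "list", geweke = "list"))

#' Simulation ground truth
#'
#' @slot genes per-gene data.frame: \code{gene}, \code{n_isoforms},
#'   \code{is_de}, \code{de_up_in} (\code{"case"}, \code{"control"} or
#'   \code{NA}), \code{is_ds}, \code{iso_up_case}, \code{iso_up_control},
#'   and pre-renormalization expected gene totals
#'   \code{total_prop_control}/\code{total_prop_case}.
#' @slot isoforms per-isoform data.frame: \code{gene}, \code{isoform},
#'   within-gene fractions \code{frac_control}/\code{frac_case}, the
#'   renormalized sampling proportions \code{prop_control}/\code{prop_case},
#'   \code{splicing_fc} (case/control within-gene fraction ratio) and
#'   \code{is_ds_isoform}.
#' @slot config the \code{\link{simulationConfig}} used.
#' @export
setClass("SimulationTruth",
    representation(genes = "data.frame", isoforms = "data.frame",
                   config = "list"))

setMethod("show", "IsoformExperiment", function(object) {
    callNextMethod()
    cat(sprintf("genes: %d | conditions: %d control / %d case\n",
                length(unique(SummarizedExperiment::rowData(object)$gene_id)),
                sum(object$condition == "control"),
                sum(object$condition == "case")))
})

setMethod("show", "VarianceTrend", function(object) {
    cat(sprintf(paste0("VarianceTrend: %d points, support [%.3f, %.3f], ",
                       "span %.2f, %d robustifying iterations\n"),
                length(object@x), object@supportRange[1L],
                object@supportRange[2L], object@span, object@iterations))
})

setMethod("show", "PosteriorDraws", function(object) {
    cat(sprintf("PosteriorDraws: %d genes, %d draws (warmup %d of %d), seed %d\n",
                length(object@draws), nDraws(object), object@warmup,
                object@steps, object@seed))
})

setMethod("show", "DuetResults", function(object) {
    tab <- object@table
    gl <- tab[tab$Isoform == "Expression", ]
    cat(sprintf("DuetResults: %d genes (%d isoform rows)\n",
                nrow(gl), sum(tab$Isoform != "Expression")))
    print(table(Category = gl$Category))
})

setMethod("show", "SimulationTruth", function(object) {
    cat(sprintf("SimulationTruth: %d genes (%d DE, %d DS), %d isoforms\n",
                nrow(object@genes), sum(object@genes$is_de),
                sum(object@genes$is_ds), nrow(object@isoforms)))
})
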