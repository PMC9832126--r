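#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

#' Tumor/normal expression container
#'
#' A thin extension of \linkS4class{SummarizedExperiment} holding a single
#' \code{log2expr} assay of log2-scale expression values (finite, non-negative)
#' together with a mandatory \code{sample_class} column in \code{colData}
#' labelling each sample \code{"tumor"} or \code{"normal"}.  Gene annotation
#' (\code{symbol}, \code{biotype}) lives in \code{rowData} when available.
#'
#' @aliases TumorNormalExperiment-class
#' @exportClass TumorNormalExperiment
setClass("TumorNormalExperiment", contains = "SummarizedExperiment")

setValidity("TumorNormalExperiment", function(object) {
    msg <- character()
    if (!"log2expr" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'log2expr' is required")
    else {
        v <- SummarizedExperiment::assay(object, "log2expr")
        if (!all(is.finite(v)))
            msg <- c(msg, "expression values must be finite")
        else if (any(v < 0))
            msg <- c(msg, "expression values must be >= 0 (log2 scale)")
    }
    if (!"sample_class" %in% colnames(SummarizedExperiment::colData(object)))
        msg <- c(msg, "colData must contain a 'sample_class' column")
    else {
        sc <- SummarizedExperiment::colData(object)$sample_class
        if (!all(sc %in% c("tumor", "normal")))
            msg <- c(msg, "sample_class values must be 'tumor' or 'normal'")
    }
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicate gene ids are not allowed")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicate sample ids are not allowed")
    if (length(msg)) msg else TRUE
})

#' Construct a TumorNormalExperiment
#'
#' @param values numeric matrix, genes x samples, log2 scale, finite and
#'   non-negative; must have row and column names.
#' @param sample_class character vector of \code{"tumor"}/\code{"normal"}
#'   labels, either parallel to the columns of \code{values} or named by
#'   sample id.
#' @param annotation optional data.frame with columns \code{gene_id},
#'   \code{symbol}, \code{biotype}; matched to rows by \code{gene_id}.
#'
#' @return A \linkS4class{TumorNormalExperiment}.
#' @examples
#' m <- matrix(abs(rnorm(20)), 4, 5,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
#' tn <- TumorNormalExperiment(m, rep(c("tumor", "normal"), c(3, 2)))
#' table(sampleClass(tn))
#' @export
TumorNormalExperiment <- function(values, sample_class, annotation = NULL) {
    if (is.null(rownames(values)) || is.null(colnames(values)))
        stop("'values' must have row (gene) and column (sample) names")
    if (!is.null(names(sample_class)))
        sample_class <- sample_class[colnames(values)]
    if (length(sample_class) != ncol(values))
        stop("'sample_class' must cover every sample column")
    cd <- S4Vectors::DataFrame(sample_class = as.character(sample_class),
                               row.names = colnames(values))
    rd <- S4Vectors::DataFrame(row.names = rownames(values))
    if (!is.null(annotation)) {
        i <- match(rownames(values), annotation$gene_id)
        rd$symbol <- as.character(annotation$symbol[i])
        rd$biotype <- as.character(annotation$biotype[i])
        rd$biotype[is.na(rd$biotype)] <- "other"
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(log2expr = values), colData = cd, rowData = rd)
    methods::new("TumorNormalExperiment", se)
}

#' Binary lncRNA-pair indicator matrix
#'
#' Stores, for every canonically oriented lncRNA pair \eqn{(A, B)} with
#' \eqn{A < B} lexicographically, the per-sample indicator
#' \eqn{\alpha = 1} when expression of A strictly exceeds expression of B
#' (ties score 0).  Being rank-based within each sample, the indicators are
#' invariant to any strictly increasing per-sample transform, hence free of
#' between-sample normalisation.
#'
#' @slot alpha binary matrix, pairs x samples; rownames are "A|B" pair ids.
#' @slot lncA,lncB character vectors naming the pair members (A < B).
#'
#' @aliases PairMatrix-class
#' @exportClass PairMatrix
setClass("PairMatrix",
    representation(alpha = "matrix", lncA = "character", lncB = "character"))

setValidity("PairMatrix", function(object) {
    msg <- character()
    a <- object@alpha
    if (length(a) && !all(a %in% c(0, 1)))
        msg <- c(msg, "alpha must contain only 0/1")
    if (nrow(a) != length(object@lncA) || nrow(a) != length(object@lncB))
        msg <- c(msg, "lncA/lncB must align with alpha rows")
    if (any(object@lncA == object@lncB))
        msg <- c(msg, "a pair cannot contain the same lncRNA twice")
    if (any(object@lncA > object@lncB))
        msg <- c(msg, "pairs must be canonically oriented (lncA < lncB)")
    ids <- paste(object@lncA, object@lncB, sep = "|")
    if (anyDuplicated(ids))
        msg <- c(msg, "each unordered pair may appear at most once")
    if (nrow(a) && !identical(rownames(a), ids))
        msg <- c(msg, "alpha rownames must equal 'A|B' pair ids")
    if (length(msg)) msg else TRUE
})

#' Stability-selection summary for penalized Cox pair selection
#'
#' @slot frequency named integer: per candidate pair, the number of
#'   cross-validated LASSO-Cox runs in which its coefficient was nonzero at
#'   the deviance-minimising lambda.
#' @slot nRuns number of randomized runs performed.
#' @slot threshold retention threshold (pairs with frequency strictly above
#'   it are retained).
#' @slot retained pair ids passing the threshold.
#' @slot selected pair ids with nonzero coefficients in the final
#'   cross-validated fit on the retained set.
#'
#' @aliases StabilitySelection-class
#' @exportClass StabilitySelection
setClass("StabilitySelection",
    representation(frequency = "integer", nRuns = "integer",
                   threshold = "numeric", retained = "character",
                   selected = "character"))

setValidity("StabilitySelection", function(object) {
    msg <- character()
    if (any(object@frequency < 0L) || any(object@frequency > object@nRuns))
        msg <- c(msg, "frequencies must lie in [0, nRuns]")
    if (!all(object@selected %in% object@retained))
        msg <- c(msg, "selected pairs must be a subset of retained pairs")
    if (length(msg)) msg else TRUE
})

#' Multivariate Cox risk model over lncRNA pair indicators
#'
#' The fitted signature: selected pairs, their log-hazard coefficients, and
#' the per-term Wald summary (coefficient, hazard ratio, 95\% CI, p-value).
#' The risk score of a sample is the exact dot product of the coefficients
#' with the sample's binary pair-indicator vector; no intercept.
#'
#' @slot pairs pair ids ("A|B").
#' @slot coefficients named numeric log-hazard coefficients, aligned with
#'   \code{pairs}.
#' @slot fitTable data.frame with columns pair, coef, hr, hr_low, hr_high, p.
#' @slot loglik partial log-likelihood at the fitted coefficients.
#'
#' @aliases RiskModel-class
#' @exportClass RiskModel
setClass("RiskModel",
    representation(pairs = "character", coefficients = "numeric",
                   fitTable = "data.frame", loglik = "numeric"))

setValidity("RiskModel", function(object) {
    msg <- character()
    if (length(object@pairs) != length(object@coefficients))
        msg <- c(msg, "pairs and coefficients must be aligned")
    if (!all(is.finite(object@coefficients)))
        msg <- c(msg, "coefficients must be finite")
    if (length(msg)) msg else TRUE
})
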