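#' Sample class labels
#'
#' @param x a \linkS4class{TumorNormalExperiment}.
#' @return Named character vector of "tumor"/"normal" labels.
#' @rdname sampleClass
#' @export
setMethod("sampleClass", "TumorNormalExperiment", function(x) {
    structure(as.character(SummarizedExperiment::colData(x)$sample_class),
              names = colnames(x))
})

#' Log2 expression values
#'
#' @param x a \linkS4class{TumorNormalExperiment}.
#' @return The genes-by-samples log2 expression matrix.
#' @export
exprValues <- function(x) {
    stopifnot(methods::is(x, "TumorNormalExperiment"))
    SummarizedExperiment::assay(x, "log2expr")
}

#' Subset to tumor (or normal) samples
#'
#' @param x a \linkS4class{TumorNormalExperiment}.
#' @param class which sample class to keep.
#' @return A \linkS4class{TumorNormalExperiment} restricted to that class.
#' @export
subsetByClass <- function(x, class = c("tumor", "normal")) {
    class <- match.arg(class)
    x[, sampleClass(x) == class]
}

#' Pair-indicator matrix accessors
#'
#' \code{alphaValues} returns the binary pairs-by-samples indicator matrix;
#' \code{pairIds} the "A|B" pair identifiers; \code{onesFraction} the exact
#' per-pair row mean of the indicators (fraction of samples where A > B).
#'
#' @param x a \linkS4class{PairMatrix}.
#' @rdname alphaValues
#' @export
setMethod("alphaValues", "PairMatrix", function(x) x@alpha)

#' @rdname pairIds
#' @param x a \linkS4class{PairMatrix} or \linkS4class{RiskModel}.
#' @export
setMethod("pairIds", "PairMatrix", function(x) rownames(x@alpha))

#' @rdname pairIds
#' @export
setMethod("pairIds", "RiskModel", function(x) x@pairs)

#' @rdname onesFraction
#' @param x a \linkS4class{PairMatrix}.
#' @export
setMethod("onesFraction", "PairMatrix", function(x) rowMeans(x@alpha))

#' Stability-selection accessors
#'
#' @param x a \linkS4class{StabilitySelection}.
#' @rdname selectionFrequency
#' @export
setMethod("selectionFrequency", "StabilitySelection", function(x) x@frequency)

#' @rdname retainedPairs
#' @param x a \linkS4class{StabilitySelection}.
#' @export
setMethod("retainedPairs", "StabilitySelection", function(x) x@retained)

#' @rdname selectedPairs
#' @param x a \linkS4class{StabilitySelection}.
#' @export
setMethod("selectedPairs", "StabilitySelection", function(x) x@selected)

#' @rdname fitTable
#' @param x a \linkS4class{RiskModel}.
#' @return \code{fitTable}: per-term Cox summary (coef, HR, 95\% CI, p).
#' @export
setMethod("fitTable", "RiskModel", function(x) x@fitTable)

#' @export
#' @rdname fitTable
#' @param object a \linkS4class{RiskModel}.
#' @param ... ignored.
setMethod("coef", "RiskModel", function(object, ...) object@coefficients)

setMethod("show", "TumorNormalExperiment", function(object) {
    sc <- sampleClass(object)
    cat("TumorNormalExperiment:", nrow(object), "genes x",
        ncol(object), "samples\n")
    cat("  tumor:", sum(sc == "tumor"), " normal:", sum(sc == "normal"), "\n")
    bt <- SummarizedExperiment::rowData(object)$biotype
    if (!is.null(bt)) {
        tb <- table(bt)
        cat("  biotypes:", paste(names(tb), tb, sep = "=", collapse = ", "),
            "\n")
    }
})

setMethod("show", "PairMatrix", function(object) {
    cat("PairMatrix:", nrow(object@alpha), "pairs x",
        ncol(object@alpha), "samples\n")
    if (nrow(object@alpha)) {
        f <- onesFraction(object)
        cat(sprintf("  ones fraction: min %.3f / median %.3f / max %.3f\n",
                    min(f), stats::median(f), max(f)))
    }
})

setMethod("show", "StabilitySelection", function(object) {
    cat("StabilitySelection:", length(object@frequency), "candidate pairs,",
        object@nRuns, "runs\n")
    cat("  retained (frequency >", object@threshold, "):",
        length(object@retained), "\n")
    cat("  selected by final CV fit:", length(object@selected), "\n")
})

setMethod("show", "RiskModel", function(object) {
    cat("RiskModel:", length(object@pairs), "lncRNA pairs\n")
    if (length(object@pairs)) {
        tab <- utils::head(object@fitTable, 5)
        print(tab, row.names = FALSE, digits = 4)
        if (nrow(object@fitTable) > 5)
            cat("  ...", nrow(object@fitTable) - 5, "more pairs\n")
    }
})
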