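#' Sample class labels of an expression container
#' @param x the object.
#' @rdname sampleClass
#' @export
setGeneric("sampleClass", function(x) standardGeneric("sampleClass"))

#' Binary pair-indicator values
#' @param x the object.
#' @rdname alphaValues
#' @export
setGeneric("alphaValues", function(x) standardGeneric("alphaValues"))

#' Pair identifiers ("A|B")
#' @param x the object.
#' @rdname pairIds
#' @export
setGeneric("pairIds", function(x) standardGeneric("pairIds"))

#' Per-pair fraction of samples with indicator 1
#' @param x the object.
#' @rdname onesFraction
#' @export
setGeneric("onesFraction", function(x) standardGeneric("onesFraction"))

#' Per-pair stability-selection frequency
#' @param x the object.
#' @rdname selectionFrequency
#' @export
setGeneric("selectionFrequency", function(x) standardGeneric("selectionFrequency"))

#' Pairs retained by the frequency threshold
#' @param x the object.
#' @rdname retainedPairs
#' @export
setGeneric("retainedPairs", function(x) standardGeneric("retainedPairs"))

#' Pairs selected by the final cross-validated fit
#' @param x the object.
#' @rdname selectedPairs
#' @export
setGeneric("selectedPairs", function(x) standardGeneric("selectedPairs"))

#' Per-term Cox fit summary table
#' @param x the object.
#' @rdname fitTable
#' @export
setGeneric("fitTable", function(x) standardGeneric("fitTable"))
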