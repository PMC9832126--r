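#' Build the 0-or-1 lncRNA pair-indicator matrix
#'
#' For every unordered pair of lncRNAs in canonical orientation (A before B
#' lexicographically) and every sample s, the indicator is
#' \eqn{\alpha(A,B,s) = 1} if expression(A, s) strictly exceeds
#' expression(B, s), else 0 (ties score 0). All \eqn{m(m-1)/2} pairs are
#' emitted. Because only the within-sample ordering matters, the matrix is
#' invariant to any strictly increasing per-sample transform of the
#' expression values.
#'
#' @param x a \linkS4class{TumorNormalExperiment} or numeric matrix
#'   restricted to the differentially expressed lncRNAs.
#' @return A \linkS4class{PairMatrix} over all pairs.
#' @export
buildPairMatrix <- function(x) {
    m <- if (methods::is(x, "TumorNormalExperiment")) exprValues(x) else x
    if (is.null(rownames(m))) stop("expression rows must be named")
    if (!all(is.finite(m))) stop("expression values must be finite")
    if (nrow(m) < 2L) stop("need >= 2 lncRNAs to form pairs")
    m <- m[order(rownames(m)), , drop = FALSE]
    idx <- utils::combn(nrow(m), 2L)
    a <- (m[idx[1L, ], , drop = FALSE] > m[idx[2L, ], , drop = FALSE]) + 0
    lncA <- rownames(m)[idx[1L, ]]
    lncB <- rownames(m)[idx[2L, ]]
    rownames(a) <- paste(lncA, lncB, sep = "|")
    colnames(a) <- colnames(m)
    methods::new("PairMatrix", alpha = a, lncA = lncA, lncB = lncB)
}

#' Keep effectively varying pairs
#'
#' Retains pairs whose indicator equals 1 in strictly more than \code{low}
#' and strictly fewer than \code{high} of the samples (defaults 20\% and
#' 80\%, both ends open). Near-constant pairs carry no ranking information
#' and would destabilise the survival fits.
#'
#' @param pm a \linkS4class{PairMatrix}.
#' @param low,high open-interval bounds on the ones fraction.
#' @return Filtered \linkS4class{PairMatrix}; empty (with a warning) if no
#'   pair qualifies.
#' @export
filterEffectivePairs <- function(pm, low = 0.20, high = 0.80) {
    stopifnot(low >= 0, low < high, high <= 1)
    f <- onesFraction(pm)
    keep <- f > low & f < high
    if (!any(keep))
        warning("no pair passed the effective-pairing filter")
    methods::new("PairMatrix",
                 alpha = pm@alpha[keep, , drop = FALSE],
                 lncA = pm@lncA[keep], lncB = pm@lncB[keep])
}

#' Subset a PairMatrix by pair id or sample id
#'
#' @param pm a \linkS4class{PairMatrix}.
#' @param pairs optional character vector of "A|B" pair ids to keep.
#' @param samples optional character vector of sample ids to keep.
#' @return The subsetted \linkS4class{PairMatrix}.
#' @export
subsetPairs <- function(pm, pairs = NULL, samples = NULL) {
    keep <- if (is.null(pairs)) seq_along(pm@lncA) else {
        i <- match(pairs, rownames(pm@alpha))
        if (anyNA(i))
            stop("pair(s) not present: ",
                 paste(pairs[is.na(i)], collapse = ", "))
        i
    }
    cols <- if (is.null(samples)) seq_len(ncol(pm@alpha)) else {
        j <- match(samples, colnames(pm@alpha))
        if (anyNA(j))
            stop("sample(s) not present: ",
                 paste(samples[is.na(j)], collapse = ", "))
        j
    }
    methods::new("PairMatrix",
                 alpha = pm@alpha[keep, cols, drop = FALSE],
                 lncA = pm@lncA[keep], lncB = pm@lncB[keep])
}

#' Serialise / read a PairMatrix as TSV
#'
#' Rows are "A|B" pair ids, columns samples, cells 0/1.
#'
#' @param pm a \linkS4class{PairMatrix}.
#' @param path file path.
#' @export
writePairMatrix <- function(pm, path) {
    df <- data.frame(pair = rownames(pm@alpha), pm@alpha, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writePairMatrix
#' @export
readPairMatrix <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    a <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(a) <- "double"
    rownames(a) <- df[[1L]]
    parts <- strsplit(df[[1L]], "|", fixed = TRUE)
    methods::new("PairMatrix", alpha = a,
                 lncA = vapply(parts, `[[`, character(1), 1L),
                 lncB = vapply(parts, `[[`, character(1), 2L))
}
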