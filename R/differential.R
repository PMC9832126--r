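#' Tumor-versus-normal differential expression of aging-related lncRNAs
#'
#' Per-gene two-sided Wilcoxon rank-sum test on log2-scale values (exact
#' enumeration for small tie-free groups, normal approximation with
#' continuity correction otherwise, as implemented by
#' \code{\link[stats]{wilcox.test}}), with Benjamini-Hochberg adjustment
#' across the tested set. The log2 fold-change is the difference of group
#' means on the log2 scale (tumor minus normal).
#'
#' @param x a \linkS4class{TumorNormalExperiment}, typically restricted to
#'   the aging-related lncRNAs so that the BH family is that screen's output.
#' @param fc_threshold log2 fold-change threshold (default 1.0, strict >).
#' @param fdr_threshold BH-adjusted p threshold (default 0.05, strict <).
#' @param absolute_fc classify by |log2fc| (default TRUE); with FALSE only
#'   the signed up rule applies.
#' @return data.frame (lncRNA, log2fc, p, fdr, direction) with direction in
#'   up/down/ns.
#' @export
differentialTest <- function(x, fc_threshold = 1.0, fdr_threshold = 0.05,
                             absolute_fc = TRUE) {
    sc <- sampleClass(x)
    if (sum(sc == "tumor") < 2L || sum(sc == "normal") < 2L)
        stop("need >= 2 tumor and >= 2 normal samples")
    m <- exprValues(x)
    tum <- m[, sc == "tumor", drop = FALSE]
    nor <- m[, sc == "normal", drop = FALSE]
    log2fc <- unname(rowMeans(tum) - rowMeans(nor))
    p <- vapply(seq_len(nrow(m)), function(i) {
        suppressWarnings(
            stats::wilcox.test(tum[i, ], nor[i, ], correct = TRUE)$p.value)
    }, numeric(1))
    fdr <- bhAdjust(p)
    up <- log2fc > fc_threshold & fdr < fdr_threshold
    down <- if (absolute_fc) {
        log2fc < -fc_threshold & fdr < fdr_threshold
    } else rep(FALSE, length(log2fc))
    direction <- rep("ns", length(log2fc))
    direction[up] <- "up"
    direction[down] <- "down"
    data.frame(lncRNA = rownames(m), log2fc = log2fc, p = p, fdr = fdr,
               direction = direction, row.names = NULL,
               stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Validated front end to \code{stats::p.adjust(method = "BH")}: inputs
#' must lie in [0, 1]; the adjusted values are returned in input order,
#' capped at 1, and satisfy \code{fdr >= p} elementwise.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return BH-adjusted p-values, same order.
#' @export
bhAdjust <- function(p) {
    if (!is.numeric(p)) stop("p-values must be numeric")
    if (any(is.na(p)) || any(p < 0) || any(p > 1))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}
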