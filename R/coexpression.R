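#' Pearson co-expression screen for aging-related lncRNAs
#'
#' Correlates every lncRNA against every aging-set gene over the shared
#' samples and flags lncRNAs whose best pairing passes both thresholds.
#' The p-value uses the exact t-transform of the product-moment coefficient,
#' \eqn{t = r \sqrt{(n-2)/(1-r^2)}} on \eqn{n-2} degrees of freedom
#' (two-sided), the same null as \code{cor.test}.
#'
#' Both thresholds are strict: a pairing passes when \eqn{r >} (or
#' \eqn{|r| >} with \code{use_absolute}) \code{r_threshold} AND
#' \eqn{p <} \code{p_threshold}. An lncRNA is aging-related when at least
#' one of its pairings passes. By default only tumor samples enter the
#' correlation, since the downstream signature concerns tumors.
#'
#' @param lnc a \linkS4class{TumorNormalExperiment} of lncRNAs.
#' @param genes a \linkS4class{TumorNormalExperiment} of coding genes.
#' @param gene_set gene set as returned by \code{\link{readGeneSet}} (list
#'   with \code{symbols}), or a character vector of symbols/ids.
#' @param r_threshold correlation threshold (default 0.7, strict >).
#' @param p_threshold p-value threshold (default 0.001, strict <).
#' @param use_absolute use |r| (default TRUE) or signed r.
#' @param samples which samples to correlate over: "tumor" (default) or
#'   "all".
#' @return list with \code{table} (all tested pairings: lncRNA, gene, r, p,
#'   n, pass) and \code{arlncRNAs} (ids of lncRNAs with >= 1 passing
#'   pairing).
#' @export
pearsonScreen <- function(lnc, genes, gene_set, r_threshold = 0.7,
                          p_threshold = 0.001, use_absolute = TRUE,
                          samples = c("tumor", "all")) {
    samples <- match.arg(samples)
    symbols <- if (is.list(gene_set)) gene_set$symbols else gene_set
    rd <- SummarizedExperiment::rowData(genes)
    hit <- rownames(genes) %in% symbols
    if (!is.null(rd$symbol)) hit <- hit | (rd$symbol %in% symbols)
    if (!any(hit)) stop("no aging-set gene found in the coding matrix")
    g <- genes[hit, ]

    shared <- intersect(colnames(lnc), colnames(g))
    if (samples == "tumor") {
        shared <- shared[sampleClass(lnc)[shared] == "tumor"]
    }
    n <- length(shared)
    if (n < 3L) stop("need >= 3 shared samples for a correlation screen")

    X <- t(exprValues(lnc)[, shared, drop = FALSE])
    Y <- t(exprValues(g)[, shared, drop = FALSE])
    sdx <- apply(X, 2L, stats::sd)
    sdy <- apply(Y, 2L, stats::sd)
    if (any(sdx == 0) || any(sdy == 0))
        warning(sum(sdx == 0) + sum(sdy == 0),
                " zero-variance vector(s); those pairings skipped")
    keep_x <- sdx > 0
    keep_y <- sdy > 0
    R <- stats::cor(X[, keep_x, drop = FALSE], Y[, keep_y, drop = FALSE])
    tstat <- abs(R) * sqrt((n - 2) / pmax(1 - R^2, .Machine$double.eps))
    tstat[abs(R) >= 1] <- Inf
    P <- 2 * stats::pt(tstat, df = n - 2, lower.tail = FALSE)

    tab <- data.frame(
        lncRNA = rep(rownames(R), times = ncol(R)),
        gene = rep(colnames(R), each = nrow(R)),
        r = as.vector(R), p = as.vector(P), n = n,
        stringsAsFactors = FALSE)
    rr <- if (use_absolute) abs(tab$r) else tab$r
    tab$pass <- rr > r_threshold & tab$p < p_threshold
    arlnc <- sort(unique(tab$lncRNA[tab$pass]))
    list(table = tab, arlncRNAs = arlnc)
}
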