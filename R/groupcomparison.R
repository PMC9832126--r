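#' High- versus low-risk comparisons over a score panel
#'
#' For every variable of a long-format score panel (immune-infiltration
#' scores, immune-checkpoint gene expression, drug IC50 estimates, ...):
#' two-sided Wilcoxon rank-sum between the high- and low-risk groups, the
#' high-minus-low median difference, and the Spearman correlation of the
#' variable with the continuous risk score. Benjamini-Hochberg adjustment
#' is applied within each panel kind, never pooled across kinds. Missing
#' values are dropped pairwise per variable; variables with fewer than two
#' non-missing values in either group are skipped with a warning.
#'
#' @param panel long-format data.frame (sample, panel_kind, variable,
#'   method, value); see \code{\link{readScorePanel}}.
#' @param scores data.frame with sample, risk_score and group columns.
#' @return data.frame (panel_kind, variable, method, n_high, n_low,
#'   statistic, p, fdr, median_diff, rho, direction).
#' @export
compareGroups <- function(panel, scores) {
    if (is.null(panel$method)) panel$method <- NA_character_
    key <- paste(panel$panel_kind, panel$variable,
                 ifelse(is.na(panel$method), "", panel$method), sep = "\r")
    res <- lapply(split(panel, key), function(d) {
        i <- match(d$sample, scores$sample)
        grp <- scores$group[i]
        rs <- scores$risk_score[i]
        ok <- !is.na(d$value) & !is.na(grp)
        hi <- d$value[ok & grp == "high"]
        lo <- d$value[ok & grp == "low"]
        if (length(hi) < 2L || length(lo) < 2L) {
            warning("variable '", d$variable[1L],
                    "' has < 2 values in a group; skipped")
            return(NULL)
        }
        wt <- suppressWarnings(stats::wilcox.test(hi, lo))
        rho <- suppressWarnings(
            stats::cor(d$value[ok], rs[ok], method = "spearman"))
        md <- stats::median(hi) - stats::median(lo)
        data.frame(panel_kind = d$panel_kind[1L], variable = d$variable[1L],
                   method = d$method[1L], n_high = length(hi),
                   n_low = length(lo), statistic = unname(wt$statistic),
                   p = unname(wt$p.value), median_diff = md, rho = rho,
                   direction = if (md > 0) "up" else if (md < 0) "down"
                               else "flat",
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res)
    if (is.null(out)) return(out)
    rownames(out) <- NULL
    out$fdr <- NA_real_
    for (k in unique(out$panel_kind)) {
        i <- out$panel_kind == k
        out$fdr[i] <- bhAdjust(out$p[i])
    }
    out[, c("panel_kind", "variable", "method", "n_high", "n_low",
            "statistic", "p", "fdr", "median_diff", "rho", "direction")]
}
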