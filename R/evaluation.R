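.kmSurvAt <- function(time, event, t0) {
    # Kaplan-Meier survival probability at t0 (product-limit).
    if (!length(time)) return(NA_real_)
    fit <- survival::survfit(survival::Surv(time, event) ~ 1)
    s <- summary(fit, times = t0, extend = TRUE)$surv
    if (!length(s)) 1 else s
}

#' Time-dependent ROC with Kaplan-Meier censoring weighting
#'
#' Cumulative/dynamic ROC at a fixed horizon t: cases are subjects with an
#' event by t, controls those still event-free at t. Sensitivity and
#' specificity at each score cutoff c are estimated from Kaplan-Meier
#' survival within the score strata,
#' \deqn{Se(c,t) = (1 - S_{X>c}(t)) P(X>c) / (1 - S(t)),\quad
#'       Sp(c,t) = S_{X \le c}(t) P(X \le c) / S(t),}
#' which reduces to the empirical case/control fractions when there is no
#' censoring. The AUC is the trapezoidal integral over all distinct score
#' cutoffs (curve anchored at (0,0) and (1,1)).
#'
#' @param scores data.frame (sample, risk_score) or named numeric vector.
#' @param clinical clinical data.frame with sample/time/event.
#' @param horizon_days evaluation horizon t in days; must lie within the
#'   observed follow-up range and have >= 1 prior event.
#' @return list (horizon, cutoffs, sensitivity, specificity, auc).
#' @export
timeDependentROC <- function(scores, clinical, horizon_days) {
    if (is.data.frame(scores))
        scores <- structure(scores$risk_score, names = scores$sample)
    shared <- intersect(names(scores), clinical$sample)
    x <- scores[shared]
    cl <- clinical[match(shared, clinical$sample), ]
    if (horizon_days > max(cl$time))
        stop("horizon exceeds the observed follow-up range")
    if (!any(cl$time <= horizon_days & cl$event == 1))
        stop("no event before the horizon")
    St <- .kmSurvAt(cl$time, cl$event, horizon_days)
    cuts <- sort(unique(x))
    sens <- spec <- numeric(length(cuts))
    for (i in seq_along(cuts)) {
        hi <- x > cuts[i]
        p_hi <- mean(hi)
        S_hi <- if (any(hi)) .kmSurvAt(cl$time[hi], cl$event[hi],
                                       horizon_days) else 1
        S_lo <- if (any(!hi)) .kmSurvAt(cl$time[!hi], cl$event[!hi],
                                        horizon_days) else 1
        sens[i] <- (1 - S_hi) * p_hi / (1 - St)
        spec[i] <- S_lo * (1 - p_hi) / St
    }
    sens <- pmin(pmax(sens, 0), 1)
    spec <- pmin(pmax(spec, 0), 1)
    # zap float noise so edge points sort onto the ROC square's edges
    snap <- function(v) {
        v[abs(v) < 1e-10] <- 0
        v[abs(v - 1) < 1e-10] <- 1
        v
    }
    sens <- snap(sens)
    spec <- snap(spec)
    # anchor: cutoff below min (everyone positive) and above max
    tpr <- c(1, sens, 0)
    fpr <- c(1, 1 - spec, 0)
    o <- order(fpr, tpr)
    auc <- sum(diff(fpr[o]) * (utils::head(tpr[o], -1) +
                               utils::tail(tpr[o], -1)) / 2)
    list(horizon = horizon_days, cutoffs = cuts, sensitivity = sens,
         specificity = spec, auc = auc)
}

#' AIC-optimal risk-score cutoff
#'
#' Scans candidate cutoffs (midpoints of consecutive sorted unique scores,
#' restricted so each dichotomized group holds at least
#' \code{min_group_frac} of the samples), fits a univariate Cox model on
#' the indicator score > c for each, and returns the cutoff minimising
#' AIC = -2 log partial likelihood + 2 (one parameter, no intercept).
#' Exact AIC ties are broken toward the candidate nearest the median score.
#'
#' @param scores data.frame (sample, risk_score) or named numeric vector.
#' @param clinical clinical data.frame.
#' @param min_group_frac minimum fraction of samples per group (default
#'   0.10).
#' @return list (cutoff, aic_profile data.frame(candidate, aic), n_high,
#'   n_low).
#' @export
aicOptimalCutoff <- function(scores, clinical, min_group_frac = 0.10) {
    if (is.data.frame(scores))
        scores <- structure(scores$risk_score, names = scores$sample)
    shared <- intersect(names(scores), clinical$sample)
    x <- scores[shared]
    cl <- clinical[match(shared, clinical$sample), ]
    if (length(unique(x)) < 2L) stop("need >= 2 distinct scores")
    if (sum(cl$event) < 1L) stop("no events in the data")
    u <- sort(unique(x))
    cand <- (utils::head(u, -1) + utils::tail(u, -1)) / 2
    n <- length(x)
    n_hi <- vapply(cand, function(c) sum(x > c), integer(1))
    ok <- n_hi >= ceiling(min_group_frac * n) &
          (n - n_hi) >= ceiling(min_group_frac * n)
    cand <- cand[ok]
    if (!length(cand))
        stop("all candidate cutoffs yield degenerate groups")
    y <- survival::Surv(cl$time, cl$event)
    aic <- vapply(cand, function(c) {
        # extreme candidates can separate the risk sets; the converged
        # partial likelihood is still the quantity the AIC scan compares
        fit <- suppressWarnings(survival::coxph(y ~ I(x > c),
                                                ties = "breslow"))
        -2 * fit$loglik[2L] + 2
    }, numeric(1))
    best <- which(aic == min(aic))
    if (length(best) > 1L)
        best <- best[which.min(abs(cand[best] - stats::median(x)))]
    cutoff <- cand[best]
    list(cutoff = cutoff,
         aic_profile = data.frame(candidate = cand, aic = aic),
         n_high = sum(x > cutoff), n_low = sum(x <= cutoff))
}

#' Assign high/low risk groups by a cutoff
#'
#' @param scores data.frame (sample, risk_score).
#' @param cutoff risk-score cutoff; score > cutoff is "high".
#' @return The data.frame with a \code{group} column added.
#' @export
assignRiskGroups <- function(scores, cutoff) {
    scores$group <- ifelse(scores$risk_score > cutoff, "high", "low")
    scores
}

#' Kaplan-Meier curves and two-group log-rank test
#'
#' Product-limit estimate per risk group plus the standard log-rank
#' statistic \eqn{(O - E)^2 / V} on 1 df.
#'
#' @param scores data.frame with sample and group columns.
#' @param clinical clinical data.frame.
#' @return list (km data.frame(group, time, surv, n_risk), chisq, p,
#'   obs, exp).
#' @export
kmLogrank <- function(scores, clinical) {
    shared <- intersect(scores$sample, clinical$sample)
    g <- scores$group[match(shared, scores$sample)]
    cl <- clinical[match(shared, clinical$sample), ]
    if (length(unique(g)) < 2L)
        stop("both risk groups must be non-empty")
    if (sum(cl$event) == 0L)
        stop("log-rank test undefined: no events in either group")
    y <- survival::Surv(cl$time, cl$event)
    sd <- survival::survdiff(y ~ g)
    fit <- survival::survfit(y ~ g)
    strata <- rep(names(fit$strata), fit$strata)
    km <- data.frame(group = sub("^g=", "", strata), time = fit$time,
                     surv = fit$surv, n_risk = fit$n.risk,
                     stringsAsFactors = FALSE)
    list(km = km, chisq = unname(sd$chisq),
         p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
         obs = sd$obs, exp = sd$exp)
}

.ordinalStage <- c("I" = 1, "II" = 2, "III" = 3, "IV" = 4)

#' Ordinal encoding of clinical covariates
#'
#' Stage I-IV to 1-4, T1-T4 to 1-4, N0-N3 to 0-3, M0/M1 to 0/1; sex coded
#' 0 = female, 1 = male; unknown/X levels become NA. Already-numeric
#' columns pass through.
#'
#' @param clinical clinical data.frame.
#' @return data.frame of numeric covariates (age, sex, stage, t_stage,
#'   n_stage, m_stage where present) with the sample column.
#' @export
encodeOrdinalClinical <- function(clinical) {
    out <- data.frame(sample = clinical$sample, stringsAsFactors = FALSE)
    num <- function(v, strip, map = NULL) {
        if (is.numeric(v)) return(v)
        v <- toupper(trimws(as.character(v)))
        v[v %in% c("", "X", "UNKNOWN", "NA")] <- NA
        v <- sub(strip, "", v)
        if (!is.null(map)) return(unname(map[v]))
        suppressWarnings(as.numeric(v))
    }
    if (!is.null(clinical$age)) out$age <- num(clinical$age, "")
    if (!is.null(clinical$sex)) {
        s <- tolower(as.character(clinical$sex))
        out$sex <- ifelse(s %in% c("male", "m", "1"), 1,
                          ifelse(s %in% c("female", "f", "0"), 0, NA))
    }
    if (!is.null(clinical$stage))
        out$stage <- num(clinical$stage, "^STAGE ?", .ordinalStage)
    if (!is.null(clinical$t_stage)) out$t_stage <- num(clinical$t_stage, "^T")
    if (!is.null(clinical$n_stage)) out$n_stage <- num(clinical$n_stage, "^N")
    if (!is.null(clinical$m_stage)) out$m_stage <- num(clinical$m_stage, "^M")
    out
}

#' Associations between risk grouping/score and clinical variables
#'
#' Per clinical variable: (i) Pearson chi-square (no continuity
#' correction by default) of the risk group against the variable's levels;
#' (ii) the risk score across levels -- Wilcoxon rank-sum for two levels,
#' Kruskal-Wallis plus all pairwise Wilcoxon contrasts for more.
#' All-missing variables are skipped with a warning.
#'
#' @param scores data.frame with sample, risk_score and group columns.
#' @param clinical clinical data.frame.
#' @param variables clinical columns to test (default: the standard set
#'   present).
#' @param correct apply Yates continuity correction in 2x2 chi-square
#'   tables (default FALSE).
#' @return data.frame (variable, comparison, test, statistic, p).
#' @export
clinicalAssociations <- function(scores, clinical,
                                 variables = intersect(
                                     c("age", "sex", "stage", "t_stage",
                                       "n_stage", "m_stage", "event"),
                                     colnames(clinical)),
                                 correct = FALSE) {
    shared <- intersect(scores$sample, clinical$sample)
    sc <- scores[match(shared, scores$sample), ]
    cl <- clinical[match(shared, clinical$sample), ]
    res <- list()
    for (v in variables) {
        val <- cl[[v]]
        if (all(is.na(val))) {
            warning("variable '", v, "' all missing; skipped")
            next
        }
        if (is.numeric(val) && length(unique(stats::na.omit(val))) > 6) {
            # continuous covariate (e.g. age): dichotomize at the median
            # for the chi-square view, keep continuous for the rank test
            val <- ifelse(val > stats::median(val, na.rm = TRUE),
                          "high", "low")
        }
        val <- factor(val)
        ok <- !is.na(val)
        if (nlevels(droplevels(val[ok])) < 2L) {
            warning("variable '", v, "' has < 2 observed levels; skipped")
            next
        }
        val <- droplevels(val[ok])
        grp <- sc$group[ok]
        rs <- sc$risk_score[ok]
        ct <- suppressWarnings(
            stats::chisq.test(table(grp, val), correct = correct))
        res[[length(res) + 1L]] <- data.frame(
            variable = v, comparison = "group vs levels", test = "chi-square",
            statistic = unname(ct$statistic), p = unname(ct$p.value),
            stringsAsFactors = FALSE)
        if (nlevels(val) == 2L) {
            wt <- stats::wilcox.test(rs ~ val)
            res[[length(res) + 1L]] <- data.frame(
                variable = v, comparison = "score across levels",
                test = "Wilcoxon", statistic = unname(wt$statistic),
                p = unname(wt$p.value), stringsAsFactors = FALSE)
        } else {
            kw <- stats::kruskal.test(rs, val)
            res[[length(res) + 1L]] <- data.frame(
                variable = v, comparison = "score across levels",
                test = "Kruskal-Wallis", statistic = unname(kw$statistic),
                p = unname(kw$p.value), stringsAsFactors = FALSE)
            lev <- levels(val)
            for (i in seq_len(length(lev) - 1L)) for (j in (i + 1):length(lev)) {
                xi <- rs[val == lev[i]]; xj <- rs[val == lev[j]]
                if (length(xi) < 2L || length(xj) < 2L) next
                wt <- suppressWarnings(stats::wilcox.test(xi, xj))
                res[[length(res) + 1L]] <- data.frame(
                    variable = v,
                    comparison = paste(lev[i], "vs", lev[j]),
                    test = "Wilcoxon", statistic = unname(wt$statistic),
                    p = unname(wt$p.value), stringsAsFactors = FALSE)
            }
        }
    }
    do.call(rbind, res)
}

.coxTable <- function(fit, terms) {
    b <- fit$coefficients
    se <- sqrt(diag(fit$var))
    data.frame(term = terms, coef = unname(b), hr = exp(unname(b)),
               hr_low = exp(unname(b) - 1.959964 * se),
               hr_high = exp(unname(b) + 1.959964 * se),
               p = 2 * stats::pnorm(-abs(unname(b) / se)),
               stringsAsFactors = FALSE)
}

#' Covariate-independence Cox analysis of the risk score
#'
#' Univariate Cox fits of survival on the risk score and each clinical
#' covariate (ordinally coded, see \code{\link{encodeOrdinalClinical}}),
#' followed by one joint multivariate fit over all of them. Collinear
#' covariates are dropped with a warning. Samples with missing covariate
#' values are excluded from the multivariate fit (complete cases).
#'
#' @param scores data.frame (sample, risk_score).
#' @param clinical clinical data.frame.
#' @param covariates encoded covariate columns to include.
#' @return list (univariate, multivariate) of per-term Cox tables.
#' @export
independenceCox <- function(scores, clinical,
                            covariates = c("age", "sex", "stage", "t_stage",
                                           "n_stage", "m_stage")) {
    enc <- encodeOrdinalClinical(clinical)
    covariates <- intersect(covariates, colnames(enc))
    shared <- intersect(scores$sample, clinical$sample)
    cl <- clinical[match(shared, clinical$sample), ]
    X <- cbind(risk_score = scores$risk_score[match(shared, scores$sample)],
               as.matrix(enc[match(shared, enc$sample), covariates,
                             drop = FALSE]))
    y <- survival::Surv(cl$time, cl$event)
    uni <- do.call(rbind, lapply(colnames(X), function(v) {
        ok <- !is.na(X[, v])
        if (length(unique(X[ok, v])) < 2L) return(NULL)
        fit <- survival::coxph(y[ok] ~ X[ok, v], ties = "breslow")
        .coxTable(fit, v)
    }))
    cc <- stats::complete.cases(X)
    Xc <- X[cc, , drop = FALSE]
    keep <- colnames(Xc)
    # drop constant and duplicated columns before the joint fit
    const <- apply(Xc, 2L, function(v) length(unique(v)) < 2L)
    dup <- duplicated(t(Xc))
    if (any(const | dup)) {
        warning("covariate(s) dropped (constant or collinear): ",
                paste(keep[const | dup], collapse = ", "))
        Xc <- Xc[, !(const | dup), drop = FALSE]
    }
    fit <- survival::coxph(y[cc] ~ Xc, ties = "breslow")
    drop_na <- is.na(fit$coefficients)
    if (any(drop_na)) {
        warning("rank-deficient design; dropped: ",
                paste(colnames(Xc)[drop_na], collapse = ", "))
    }
    multi <- .coxTable(
        list(coefficients = fit$coefficients[!drop_na],
             var = fit$var[!drop_na, !drop_na, drop = FALSE]),
        colnames(Xc)[!drop_na])
    list(univariate = uni, multivariate = multi)
}

#' Basic evaluation plots
#'
#' \code{plotTimeROC} draws one or more time-dependent ROC curves;
#' \code{plotKMGroups} the Kaplan-Meier curves per risk group;
#' \code{plotRiskScores} the sorted risk-score scatter coloured by group.
#'
#' @param rocs a single result of \code{\link{timeDependentROC}} or a list
#'   of them.
#' @param file optional output file (PNG by extension); NULL plots to the
#'   active device.
#' @return invisible NULL.
#' @rdname evaluationPlots
#' @export
plotTimeROC <- function(rocs, file = NULL) {
    if (!is.null(rocs$auc)) rocs <- list(rocs)
    if (!is.null(file)) grDevices::png(file, width = 600, height = 600)
    graphics::plot(c(0, 1), c(0, 1), type = "l", lty = 2, col = "grey",
                   xlab = "1 - specificity", ylab = "sensitivity")
    cols <- seq_along(rocs) + 1L
    for (i in seq_along(rocs)) {
        r <- rocs[[i]]
        o <- order(1 - r$specificity, r$sensitivity)
        graphics::lines(c(0, (1 - r$specificity)[o], 1),
                        c(0, r$sensitivity[o], 1), col = cols[i])
    }
    graphics::legend("bottomright", bty = "n", col = cols, lty = 1,
        legend = vapply(rocs, function(r)
            sprintf("%g days: AUC %.3f", r$horizon, r$auc), character(1)))
    if (!is.null(file)) grDevices::dev.off()
    invisible(NULL)
}

#' @rdname evaluationPlots
#' @param scores data.frame with sample, risk_score, group.
#' @param clinical clinical data.frame.
#' @export
plotKMGroups <- function(scores, clinical, file = NULL) {
    shared <- intersect(scores$sample, clinical$sample)
    g <- factor(scores$group[match(shared, scores$sample)])
    cl <- clinical[match(shared, clinical$sample), ]
    fit <- survival::survfit(
        survival::Surv(cl$time, cl$event) ~ g)
    if (!is.null(file)) grDevices::png(file, width = 600, height = 600)
    graphics::plot(fit, col = c(2, 4), xlab = "days",
                   ylab = "survival probability")
    graphics::legend("bottomleft", bty = "n", col = c(2, 4), lty = 1,
                     legend = levels(g))
    if (!is.null(file)) grDevices::dev.off()
    invisible(NULL)
}

#' @rdname evaluationPlots
#' @export
plotRiskScores <- function(scores, file = NULL) {
    o <- order(scores$risk_score)
    if (!is.null(file)) grDevices::png(file, width = 700, height = 400)
    graphics::plot(seq_along(o), scores$risk_score[o],
                   col = ifelse(scores$group[o] == "high", 2, 4),
                   pch = 16, cex = 0.5, xlab = "sample rank",
                   ylab = "risk score")
    if (!is.null(file)) grDevices::dev.off()
    invisible(NULL)
}
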