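#' @importFrom survival Surv coxph survfit survdiff
NULL

.alignPairsClinical <- function(pm, clinical) {
    shared <- intersect(colnames(pm@alpha), clinical$sample)
    if (length(shared) < 2L)
        stop("pair matrix and clinical table share too few samples")
    list(alpha = pm@alpha[, shared, drop = FALSE],
         clinical = clinical[match(shared, clinical$sample), , drop = FALSE])
}

#' Univariate Cox screen of pair indicators
#'
#' One proportional-hazards fit per pair (Breslow tie handling, Newton
#' iteration as in \code{survival::coxph}) of survival on the binary
#' indicator; the Wald two-sided p decides passage. Constant pairs and
#' fits with unbounded coefficients (monotone likelihood / perfect
#' separation) are excluded with a warning.
#'
#' @param pm a \linkS4class{PairMatrix}.
#' @param clinical clinical data.frame with sample/time/event.
#' @param p_threshold Wald p threshold (default 0.05, strict <).
#' @param ties tie-handling method for the partial likelihood.
#' @return data.frame (pair, coef, hr, hr_low, hr_high, p, loglik, pass);
#'   rows are all testable pairs, \code{pass} marks the screen survivors.
#' @export
univariateCoxScreen <- function(pm, clinical, p_threshold = 0.05,
                                ties = c("breslow", "efron")) {
    ties <- match.arg(ties)
    al <- .alignPairsClinical(pm, clinical)
    if (sum(al$clinical$event) < 2L)
        stop("need >= 2 events for a Cox screen")
    y <- survival::Surv(al$clinical$time, al$clinical$event)
    ctrl <- survival::coxph.control()
    n_const <- 0L
    n_diverged <- 0L
    rows <- lapply(seq_len(nrow(al$alpha)), function(i) {
        xi <- as.numeric(al$alpha[i, ])
        if (stats::var(xi) == 0) {
            n_const <<- n_const + 1L
            return(NULL)
        }
        # single-covariate Newton fit on the partial likelihood; the
        # formula-free entry point keeps a ~5000-pair screen fast
        fit <- suppressWarnings(
            survival::coxph.fit(matrix(xi, ncol = 1L), y, strata = NULL,
                                offset = NULL, init = NULL,
                                control = ctrl, weights = NULL,
                                method = ties, rownames = NULL))
        b <- unname(fit$coefficients)
        se <- sqrt(fit$var[1L, 1L])
        # monotone likelihood / perfect separation: unbounded coefficient
        if (!is.finite(b) || !is.finite(se) || abs(b) > 15 || se > 50) {
            n_diverged <<- n_diverged + 1L
            return(NULL)
        }
        data.frame(pair = rownames(al$alpha)[i], coef = b, hr = exp(b),
                   hr_low = exp(b - 1.959964 * se),
                   hr_high = exp(b + 1.959964 * se),
                   p = 2 * stats::pnorm(-abs(b / se)),
                   loglik = fit$loglik[2L], stringsAsFactors = FALSE)
    })
    if (n_const > 0L)
        warning(n_const, " constant pair(s) skipped")
    if (n_diverged > 0L)
        warning(n_diverged, " pair(s) with non-convergent fits excluded")
    out <- do.call(rbind, rows)
    if (is.null(out)) stop("no pair could be fitted")
    out$pass <- out$p < p_threshold
    rownames(out) <- NULL
    out
}

.stratifiedFolds <- function(event, nfolds) {
    fold <- integer(length(event))
    for (grp in unique(event)) {
        idx <- which(event == grp)
        fold[idx] <- sample(rep_len(seq_len(nfolds), length(idx)))
    }
    fold
}

#' Repeated cross-validated LASSO-Cox stability selection
#'
#' Each run draws a fresh event-stratified fold assignment, fits the
#' L1-penalised Cox path by \code{glmnet}, picks the lambda minimising
#' cross-validated partial-likelihood deviance, and counts the pairs with
#' nonzero coefficients there. After \code{n_runs} runs, pairs selected in
#' strictly more than \code{retention_threshold} runs are retained, and one
#' final cross-validated fit on the retained set yields the selected model
#' pairs (nonzero coefficients at its lambda-min).
#'
#' With \code{n_runs = 1} and \code{retention_threshold = 0} the procedure
#' reduces to a single CV-LASSO run.
#'
#' @param pm a \linkS4class{PairMatrix} restricted to the univariate-screen
#'   survivors.
#' @param clinical clinical data.frame.
#' @param n_runs number of randomized runs (default 1000).
#' @param retention_threshold retention count threshold (default 100,
#'   strict >).
#' @param folds number of CV folds per run (default 10).
#' @param seed integer master seed; run r uses seed + r.
#' @param dfmax path truncation: the lambda path stops once this many
#'   pairs have entered (a pure speed guard; if the cross-validated
#'   minimum lands on the truncated end, the run is automatically redone
#'   with the full path so the lambda-min rule is exact).
#' @return A \linkS4class{StabilitySelection}.
#' @export
stabilityLasso <- function(pm, clinical, n_runs = 1000,
                           retention_threshold = 100, folds = 10, seed = 1,
                           dfmax = 100) {
    al <- .alignPairsClinical(pm, clinical)
    if (nrow(al$alpha) < 2L)
        stop("need >= 2 candidate pairs for selection")
    if (sum(al$clinical$event) < folds)
        stop("need at least as many events as folds")
    x <- t(al$alpha)
    y <- survival::Surv(al$clinical$time, al$clinical$event)
    freq <- integer(nrow(al$alpha))
    names(freq) <- rownames(al$alpha)
    cvLassoMin <- function(xx, foldid) {
        cv <- glmnet::cv.glmnet(xx, y, family = "cox", foldid = foldid,
                                type.measure = "deviance", dfmax = dfmax)
        # redo with the untruncated path if the CV minimum sits on the
        # truncated end, so lambda-min is the true deviance minimiser
        if (cv$lambda.min == min(cv$lambda) && length(cv$lambda) < 100L &&
            ncol(xx) > dfmax)
            cv <- glmnet::cv.glmnet(xx, y, family = "cox", foldid = foldid,
                                    type.measure = "deviance")
        cv
    }
    for (r in seq_len(n_runs)) {
        set.seed(seed + r)
        foldid <- .stratifiedFolds(al$clinical$event, folds)
        cv <- cvLassoMin(x, foldid)
        b <- as.vector(stats::coef(cv, s = "lambda.min"))
        freq <- freq + (b != 0)
    }
    retained <- names(freq)[freq > retention_threshold]
    if (!length(retained))
        stop("no pair exceeded the retention threshold (", retention_threshold,
             "/", n_runs, " runs); review effect sizes or lower the threshold")
    if (length(retained) >= 2L) {
        set.seed(seed)
        foldid <- .stratifiedFolds(al$clinical$event, folds)
        cv2 <- cvLassoMin(x[, retained, drop = FALSE], foldid)
        b2 <- as.vector(stats::coef(cv2, s = "lambda.min"))
        selected <- retained[b2 != 0]
        if (!length(selected)) selected <- retained
    } else {
        selected <- retained
    }
    methods::new("StabilitySelection", frequency = freq,
                 nRuns = as.integer(n_runs),
                 threshold = as.numeric(retention_threshold),
                 retained = retained, selected = selected)
}

#' Final multivariate Cox fit over selected pairs
#'
#' Joint proportional-hazards fit (Breslow ties) of survival on the selected
#' pair indicators. Pairs whose indicator vectors are identical across
#' samples are deduplicated beforehand (lexicographically first kept, with
#' a warning); constant pairs are dropped likewise. Per term the table
#' reports the log-hazard coefficient, HR = exp(coef), the Wald 95\% CI
#' exp(coef +/- 1.96 se) and the Wald two-sided p.
#'
#' @param pm a \linkS4class{PairMatrix}.
#' @param clinical clinical data.frame.
#' @param pairs pair ids to fit (default: all pairs in \code{pm}).
#' @param ties tie-handling method.
#' @return A \linkS4class{RiskModel}.
#' @export
fitMultivariateCox <- function(pm, clinical, pairs = pairIds(pm),
                               ties = c("breslow", "efron")) {
    ties <- match.arg(ties)
    if (!length(pairs)) stop("selected pair set is empty")
    pm <- subsetPairs(pm, pairs = pairs)
    al <- .alignPairsClinical(pm, clinical)
    a <- al$alpha
    keep <- apply(a, 1L, stats::var) > 0
    if (any(!keep)) {
        warning(sum(!keep), " constant pair(s) dropped before the joint fit")
        a <- a[keep, , drop = FALSE]
    }
    dup <- duplicated(as.data.frame(a))
    if (any(dup)) {
        warning(sum(dup), " pair(s) with identical indicators deduplicated")
        a <- a[!dup, , drop = FALSE]
    }
    if (!nrow(a)) stop("no non-degenerate pair left to fit")
    x <- t(a)
    y <- survival::Surv(al$clinical$time, al$clinical$event)
    fit <- survival::coxph(y ~ x, ties = ties)
    if (is.null(fit$coefficients) || any(!is.finite(fit$coefficients)))
        stop("multivariate Cox fit did not converge; iterations: ", fit$iter)
    b <- unname(fit$coefficients)
    se <- sqrt(diag(fit$var))
    tab <- data.frame(
        pair = rownames(a), coef = b, hr = exp(b),
        hr_low = exp(b - 1.959964 * se), hr_high = exp(b + 1.959964 * se),
        p = 2 * stats::pnorm(-abs(b / se)),
        stringsAsFactors = FALSE)
    methods::new("RiskModel", pairs = rownames(a),
                 coefficients = structure(b, names = rownames(a)),
                 fitTable = tab, loglik = unname(fit$loglik[2L]))
}

#' Per-sample risk scores
#'
#' The risk score of a sample is the exact linear functional
#' \eqn{\sum_i \beta_i \alpha_i(s)} of its binary pair indicators, with no
#' intercept.
#'
#' @param model a \linkS4class{RiskModel}.
#' @param pm a \linkS4class{PairMatrix} containing every model pair.
#' @return data.frame (sample, risk_score).
#' @export
computeRiskScores <- function(model, pm) {
    missing <- setdiff(model@pairs, rownames(pm@alpha))
    if (length(missing))
        stop("pair(s) absent from the pair matrix: ",
             paste(missing, collapse = ", "))
    a <- pm@alpha[model@pairs, , drop = FALSE]
    score <- drop(crossprod(a, model@coefficients))
    data.frame(sample = colnames(pm@alpha), risk_score = unname(score),
               stringsAsFactors = FALSE)
}

#' Reference LUAD lncRNA-pair signature
#'
#' The multivariate Cox summary (coefficient, hazard ratio, 95\% CI,
#' p-value) of a published lung-adenocarcinoma aging-lncRNA pair signature,
#' shipped as a plain-text table. Useful as a worked example of the
#' \linkS4class{RiskModel} quantities and for consistency checks
#' (HR = exp(coef)).
#'
#' @return data.frame (pair, coef, hr, hr_low, hr_high, p).
#' @export
referencePairSignature <- function() {
    path <- system.file("extdata", "luad_reference_pair_signature.tsv",
                        package = "lncPairRisk", mustWork = TRUE)
    utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Build a RiskModel from a coefficient table
#'
#' @param table data.frame with columns pair and coef (optionally hr,
#'   hr_low, hr_high, p).
#' @return A \linkS4class{RiskModel}.
#' @export
riskModelFromTable <- function(table) {
    stopifnot(all(c("pair", "coef") %in% colnames(table)))
    methods::new("RiskModel", pairs = table$pair,
                 coefficients = structure(table$coef, names = table$pair),
                 fitTable = as.data.frame(table), loglik = NA_real_)
}
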