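#' Default pipeline configuration
#'
#' Every stage threshold has a named key defaulting to the headline
#' workflow values: co-expression r > 0.7 at p < 0.001, |log2FC| > 1 at
#' FDR < 0.05, effective-pair bounds (0.2, 0.8), univariate p < 0.05,
#' 1000 stability runs with retention frequency > 100, 10 folds, ROC
#' horizons 1/3/5 years (365-day years), minimum follow-up 1 day.
#' The list round-trips losslessly through YAML
#' (\code{\link{readPipelineConfig}} / \code{\link{writePipelineConfig}}).
#'
#' @param ... overrides of named defaults.
#' @return A named list.
#' @export
defaultPipelineConfig <- function(...) {
    cfg <- list(
        r_threshold = 0.7, p_threshold = 0.001, use_absolute = TRUE,
        fc_threshold = 1.0, fdr_threshold = 0.05,
        pair_low = 0.20, pair_high = 0.80,
        univariate_p = 0.05,
        n_runs = 1000, retention_threshold = 100, folds = 10,
        horizons = c(365, 1095, 1825),
        min_followup_days = 1,
        min_group_frac = 0.10,
        seed = 1)
    ov <- list(...)
    bad <- setdiff(names(ov), names(cfg))
    if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
    cfg[names(ov)] <- ov
    stopifnot(cfg$r_threshold >= 0, cfg$r_threshold <= 1,
              cfg$p_threshold > 0, cfg$p_threshold <= 1,
              cfg$pair_low >= 0, cfg$pair_low < cfg$pair_high,
              cfg$pair_high <= 1, cfg$n_runs >= 1,
              cfg$retention_threshold >= 0, cfg$folds >= 2)
    cfg
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @rdname pipelineConfigIO
#' @export
readPipelineConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    do.call(defaultPipelineConfig, cfg)
}

#' @rdname pipelineConfigIO
#' @param config a config list.
#' @export
writePipelineConfig <- function(config, path) {
    yaml::write_yaml(config, path)
    invisible(path)
}

#' Run the full lncRNA-pair prognostic pipeline
#'
#' Executes the stages in order: co-expression screen of lncRNAs against
#' the aging gene set (tumor samples), tumor-vs-normal differential
#' expression of the screen survivors, exhaustive 0/1 pair construction
#' and effective-pair filtering on tumor samples, univariate Cox screen,
#' repeated cross-validated LASSO-Cox stability selection, final
#' multivariate Cox model, per-sample risk scores, AIC-optimal cutoff and
#' group assignment, time-dependent ROC at the configured horizons,
#' Kaplan-Meier/log-rank comparison, clinical association and
#' covariate-independence analyses, and (if a score panel is supplied)
#' high-vs-low group comparisons.
#'
#' Stage outputs are pure functions of (inputs, config, seed). When
#' \code{out_dir} is given, every stage table is written as TSV together
#' with a manifest JSON recording thresholds, seed, stage row counts and
#' output file checksums.
#'
#' @param expr a \linkS4class{TumorNormalExperiment} containing coding
#'   genes and lncRNAs (biotypes in rowData or \code{annotation}).
#' @param gene_set aging gene set (list with \code{symbols} or character
#'   vector).
#' @param clinical clinical data.frame (sample, time, event, covariates).
#' @param annotation optional annotation data.frame.
#' @param panel optional long-format score panel.
#' @param config pipeline configuration, see
#'   \code{\link{defaultPipelineConfig}}.
#' @param out_dir optional output directory for stage tables + manifest.
#' @return list with every stage result plus a \code{counts} log
#'   (arlncRNAs, DE up/down, pairs pre/post filter, univariate survivors,
#'   retained/selected pairs, model size, group sizes).
#' @export
runPipeline <- function(expr, gene_set, clinical, annotation = NULL,
                        panel = NULL, config = defaultPipelineConfig(),
                        out_dir = NULL) {
    counts <- list()
    stage <- function(name, fun) {
        tryCatch(fun(), error = function(e)
            stop("pipeline halted at stage '", name, "': ",
                 conditionMessage(e), call. = FALSE))
    }
    parts <- stage("split_biotype", function()
        splitByBiotype(expr, annotation))
    clinical <- stage("filter_followup", function()
        filterFollowup(clinical, config$min_followup_days))

    screen <- stage("coexpression", function()
        pearsonScreen(parts$lncRNA, parts$mRNA, gene_set,
                      r_threshold = config$r_threshold,
                      p_threshold = config$p_threshold,
                      use_absolute = config$use_absolute))
    counts$arlncRNAs <- length(screen$arlncRNAs)
    if (!counts$arlncRNAs)
        stop("pipeline halted at stage 'coexpression': no arlncRNA found")

    de <- stage("differential_expression", function()
        differentialTest(parts$lncRNA[screen$arlncRNAs, ],
                         fc_threshold = config$fc_threshold,
                         fdr_threshold = config$fdr_threshold))
    de_ids <- de$lncRNA[de$direction != "ns"]
    counts$de_up <- sum(de$direction == "up")
    counts$de_down <- sum(de$direction == "down")
    if (length(de_ids) < 2L)
        stop("pipeline halted at stage 'differential_expression': ",
             "fewer than 2 DEarlncRNAs")

    tumor_lnc <- subsetByClass(parts$lncRNA[de_ids, ], "tumor")
    pm_all <- stage("pair_construction", function()
        buildPairMatrix(tumor_lnc))
    counts$pairs_total <- length(pairIds(pm_all))
    pm <- stage("effective_pair_filter", function()
        filterEffectivePairs(pm_all, config$pair_low, config$pair_high))
    counts$pairs_effective <- length(pairIds(pm))

    uni <- stage("univariate_cox", function()
        univariateCoxScreen(pm, clinical, p_threshold = config$univariate_p))
    counts$univariate_prognostic <- sum(uni$pass)
    if (counts$univariate_prognostic < 2L)
        stop("pipeline halted at stage 'univariate_cox': ",
             "fewer than 2 prognostic pairs")

    sel <- stage("stability_lasso", function()
        stabilityLasso(subsetPairs(pm, pairs = uni$pair[uni$pass]), clinical,
                       n_runs = config$n_runs,
                       retention_threshold = config$retention_threshold,
                       folds = config$folds, seed = config$seed))
    counts$retained <- length(retainedPairs(sel))
    counts$selected <- length(selectedPairs(sel))

    model <- stage("multivariate_cox", function()
        fitMultivariateCox(pm, clinical, pairs = selectedPairs(sel)))
    counts$model_pairs <- length(pairIds(model))

    scores <- stage("risk_scores", function() computeRiskScores(model, pm))
    cut <- stage("aic_cutoff", function()
        aicOptimalCutoff(scores, clinical,
                         min_group_frac = config$min_group_frac))
    scores <- assignRiskGroups(scores, cut$cutoff)
    counts$n_high <- sum(scores$group == "high")
    counts$n_low <- sum(scores$group == "low")

    horizons <- config$horizons[config$horizons <= max(clinical$time)]
    rocs <- lapply(horizons, function(h)
        stage("time_dependent_roc", function()
            timeDependentROC(scores, clinical, h)))
    names(rocs) <- paste0("d", horizons)

    km <- stage("km_logrank", function() kmLogrank(scores, clinical))
    assoc <- stage("clinical_associations", function()
        clinicalAssociations(scores, clinical))
    indep <- stage("independence_cox", function()
        independenceCox(scores, clinical))
    comparisons <- if (!is.null(panel))
        stage("group_comparison", function() compareGroups(panel, scores))
    else NULL

    result <- list(screen = screen, de = de, pair_matrix = pm,
                   univariate = uni, stability = sel, model = model,
                   scores = scores, cutoff = cut, rocs = rocs, km = km,
                   associations = assoc, independence = indep,
                   comparisons = comparisons, counts = counts,
                   config = config)
    if (!is.null(out_dir)) .writePipelineArtifacts(result, out_dir)
    result
}

.writePipelineArtifacts <- function(result, out_dir) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    w <- function(df, name) {
        p <- file.path(out_dir, name)
        utils::write.table(df, p, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        p
    }
    files <- c(
        w(result$screen$table, "coexpression_pairs.tsv"),
        w(data.frame(arlncRNA = result$screen$arlncRNAs), "arlncRNAs.tsv"),
        w(result$de, "differential_expression.tsv"),
        w(result$univariate, "univariate_cox.tsv"),
        w(data.frame(pair = names(selectionFrequency(result$stability)),
                     frequency = unname(selectionFrequency(result$stability))),
          "stability_frequency.tsv"),
        w(fitTable(result$model), "risk_model.tsv"),
        w(result$scores, "risk_scores.tsv"),
        w(result$cutoff$aic_profile, "aic_profile.tsv"),
        w(result$km$km, "km_curves.tsv"),
        w(result$associations, "clinical_associations.tsv"),
        w(result$independence$univariate, "independence_univariate.tsv"),
        w(result$independence$multivariate, "independence_multivariate.tsv"))
    if (!is.null(result$comparisons))
        files <- c(files, w(result$comparisons, "group_comparisons.tsv"))
    pmp <- file.path(out_dir, "pair_matrix.tsv")
    writePairMatrix(result$pair_matrix, pmp)
    files <- c(files, pmp)
    manifest <- list(
        package_version = as.character(utils::packageVersion("lncPairRisk")),
        config = result$config,
        counts = result$counts,
        aucs = lapply(result$rocs, `[[`, "auc"),
        cutoff = result$cutoff$cutoff,
        files = structure(as.list(unname(tools::md5sum(files))),
                          names = basename(files)))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(out_dir)
}
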