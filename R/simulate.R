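#' Synthetic-cohort configuration
#'
#' Collects every knob of the synthetic-data generator, validated once.
#' Defaults encode the study conditions the pipeline is tested under: a
#' 400-tumor / 50-normal cohort, 120 lncRNAs co-expressed with an aging
#' gene panel at target Pearson r = 0.8, 99 up- and 12 down-shifted
#' differentially expressed lncRNAs at |log2FC| = 2, and exponential
#' proportional-hazards survival driven by 3 signal pairs with log-hazard
#' coefficients (1.5, -1.0, 0.8), yielding an event fraction around 0.6.
#'
#' @param n_tumor,n_normal sample counts per class.
#' @param n_aging_genes number of aging-panel coding genes.
#' @param n_lncRNA total number of lncRNAs.
#' @param n_linked_lncRNA lncRNAs co-expressed with an aging gene
#'   (must be <= n_lncRNA).
#' @param n_de_up,n_de_down planted differentially expressed lncRNAs
#'   (up/down in tumors); their sum must be <= n_linked_lncRNA.
#' @param de_log2fc mean tumor shift magnitude in log2 units.
#' @param coexpr_r target Pearson correlation in (0, 1] between a linked
#'   lncRNA and its partner aging gene.
#' @param n_signal_pairs number of pair indicators that drive survival.
#' @param true_coefficients log-hazard coefficient per signal pair.
#' @param baseline_hazard exponential baseline hazard per day.
#' @param censoring_rate independent exponential censoring rate per day
#'   (0 disables random censoring).
#' @param max_followup_days administrative censoring horizon (may be Inf).
#' @param stage_link strength of the optional association between tumor
#'   stage and the survival linear predictor (0 = independent).
#' @param seed integer master seed; all generator draws derive from it.
#' @return A validated config (classed list).
#' @export
syntheticConfig <- function(n_tumor = 400, n_normal = 50,
                            n_aging_genes = 50, n_lncRNA = 160,
                            n_linked_lncRNA = 120, n_de_up = 99,
                            n_de_down = 12, de_log2fc = 2,
                            coexpr_r = 0.8, n_signal_pairs = 3,
                            true_coefficients = c(1.5, -1.0, 0.8),
                            baseline_hazard = 5e-4, censoring_rate = 5e-4,
                            max_followup_days = 3650, stage_link = 0,
                            seed = 1) {
    cfg <- list(n_tumor = n_tumor, n_normal = n_normal,
                n_aging_genes = n_aging_genes, n_lncRNA = n_lncRNA,
                n_linked_lncRNA = n_linked_lncRNA, n_de_up = n_de_up,
                n_de_down = n_de_down, de_log2fc = de_log2fc,
                coexpr_r = coexpr_r, n_signal_pairs = n_signal_pairs,
                true_coefficients = true_coefficients,
                baseline_hazard = baseline_hazard,
                censoring_rate = censoring_rate,
                max_followup_days = max_followup_days,
                stage_link = stage_link, seed = as.integer(seed))
    n_de <- n_de_up + n_de_down
    if (n_tumor < 1 || n_normal < 1)
        stop("sample counts must be positive")
    if (n_linked_lncRNA > n_lncRNA)
        stop("n_linked_lncRNA must be <= n_lncRNA")
    if (n_de > n_linked_lncRNA)
        stop("n_de_up + n_de_down must be <= n_linked_lncRNA")
    if (n_signal_pairs > n_de * (n_de - 1) / 2)
        stop("n_signal_pairs exceeds the number of DE pairs")
    if (length(true_coefficients) != n_signal_pairs)
        stop("true_coefficients must have one entry per signal pair")
    if (coexpr_r <= 0 || coexpr_r > 1)
        stop("coexpr_r must lie in (0, 1]")
    if (baseline_hazard <= 0) stop("baseline_hazard must be positive")
    if (censoring_rate < 0) stop("censoring_rate must be >= 0")
    structure(cfg, class = "lncpair_sim_config")
}

.padIds <- function(prefix, n) sprintf("%s%03d", prefix, seq_len(n))

#' Generate a synthetic expression cohort with known ground truth
#'
#' Aging genes follow a 5-factor latent model (unit variance around a
#' baseline of 6 log2 units). Each linked lncRNA is
#' \eqn{r u + \sqrt{1 - r^2}\,\epsilon} around the same baseline, where u
#' is its partner aging gene's standardized signal, so the expected
#' Pearson correlation is \code{coexpr_r} (exactly 1 when
#' \code{coexpr_r = 1}). The first \code{n_de_up} linked lncRNAs gain
#' \code{+de_log2fc} in tumor samples and the next \code{n_de_down} lose
#' it; remaining lncRNAs are independent noise. The whole matrix is
#' shifted by a common constant so the minimum value is >= 0 (mimicking
#' log2(x+1) data; correlations, fold-changes and pair orderings are
#' unaffected). Signal pairs are disjoint pairs of up-shifted DE lncRNAs;
#' their per-tumor-sample indicators (computed exactly as
#' \code{\link{buildPairMatrix}} does) define the survival linear
#' predictor.
#'
#' Draw order under the single seeded generator: latent factors, aging
#' loadings, aging idiosyncratic noise, linked-lncRNA noise, unlinked
#' lncRNA values. Identical seeds give bit-identical tables.
#'
#' @param config a \code{\link{syntheticConfig}}.
#' @return list with \code{expr} (\linkS4class{TumorNormalExperiment} over
#'   aging genes + lncRNAs), \code{annotation}, \code{gene_set} (the aging
#'   panel), and \code{truth} (planted DE sets, signal pairs,
#'   coefficients, per-tumor-sample linear predictor).
#' @export
simulateExpression <- function(config) {
    stopifnot(inherits(config, "lncpair_sim_config"))
    set.seed(config$seed)
    n_s <- config$n_tumor + config$n_normal
    samples <- c(.padIds("TUM", config$n_tumor),
                 .padIds("NOR", config$n_normal))
    s_class <- rep(c("tumor", "normal"), c(config$n_tumor, config$n_normal))
    aging_ids <- .padIds("AGEG", config$n_aging_genes)
    lnc_ids <- .padIds("LNC", config$n_lncRNA)

    K <- 5L
    Fmat <- matrix(stats::rnorm(K * n_s), K, n_s)
    W <- matrix(stats::rnorm(config$n_aging_genes * K),
                config$n_aging_genes, K)
    W <- W / sqrt(rowSums(W^2))
    common <- W %*% Fmat
    idio <- matrix(stats::rnorm(config$n_aging_genes * n_s),
                   config$n_aging_genes, n_s)
    u_aging <- sqrt(0.7) * common + sqrt(0.3) * idio   # unit variance
    aging <- 6 + u_aging

    r <- config$coexpr_r
    partner <- ((seq_len(config$n_linked_lncRNA) - 1L) %%
                config$n_aging_genes) + 1L
    eps <- matrix(stats::rnorm(config$n_linked_lncRNA * n_s),
                  config$n_linked_lncRNA, n_s)
    linked <- 6 + r * u_aging[partner, , drop = FALSE] + sqrt(1 - r^2) * eps
    n_unlinked <- config$n_lncRNA - config$n_linked_lncRNA
    unlinked <- 6 + matrix(stats::rnorm(n_unlinked * n_s), n_unlinked, n_s)
    lnc <- rbind(linked, unlinked)
    rownames(lnc) <- lnc_ids
    rownames(aging) <- aging_ids

    n_de <- config$n_de_up + config$n_de_down
    de_up <- lnc_ids[seq_len(config$n_de_up)]
    de_down <- lnc_ids[config$n_de_up + seq_len(config$n_de_down)]
    tum_cols <- which(s_class == "tumor")
    lnc[de_up, tum_cols] <- lnc[de_up, tum_cols] + config$de_log2fc
    if (config$n_de_down > 0)
        lnc[de_down, tum_cols] <- lnc[de_down, tum_cols] - config$de_log2fc

    vals <- rbind(aging, lnc)
    colnames(vals) <- samples
    shift <- min(0, min(vals))
    vals <- vals - shift

    annotation <- data.frame(
        gene_id = c(aging_ids, lnc_ids),
        symbol = c(aging_ids, lnc_ids),
        biotype = rep(c("protein_coding", "lncRNA"),
                      c(config$n_aging_genes, config$n_lncRNA)),
        stringsAsFactors = FALSE)
    expr <- TumorNormalExperiment(vals, s_class, annotation = annotation)

    np <- config$n_signal_pairs
    if (np > 0) {
        pool <- c(de_up, de_down)
        if (2 * np <= length(pool)) {
            pr <- matrix(pool[seq_len(2 * np)], nrow = 2)
        } else {
            pr <- utils::combn(pool, 2)[, seq_len(np), drop = FALSE]
        }
        pr <- apply(pr, 2L, sort)              # canonical orientation
        signal_pairs <- paste(pr[1L, ], pr[2L, ], sep = "|")
        tum_expr <- vals[unique(as.vector(pr)), s_class == "tumor",
                         drop = FALSE]
        pm <- subsetPairs(buildPairMatrix(tum_expr), pairs = signal_pairs)
        lp <- drop(crossprod(alphaValues(pm), config$true_coefficients))
        names(lp) <- colnames(alphaValues(pm))
    } else {
        signal_pairs <- character()
        lp <- structure(rep(0, config$n_tumor),
                        names = samples[s_class == "tumor"])
    }
    truth <- structure(list(
        de_up = de_up, de_down = de_down,
        de_lncRNA_ids = c(de_up, de_down),
        signal_pairs = signal_pairs,
        signal_coefficients = structure(config$true_coefficients,
                                        names = signal_pairs),
        per_sample_linear_predictor = lp), class = "lncpair_sim_truth")
    gene_set <- list(name = "aging_panel", symbols = aging_ids)
    list(expr = expr, annotation = annotation, gene_set = gene_set,
         truth = truth)
}

#' Generate survival and clinical covariates from planted pair effects
#'
#' Event times are exponential with per-sample hazard
#' \eqn{h_0 \exp(\sum_k \beta_k \alpha_k(s))}, where the pair indicators
#' come from the expression matrix exactly as in
#' \code{\link{buildPairMatrix}}. Independent exponential censoring at
#' \code{censoring_rate} and administrative censoring at
#' \code{max_followup_days} apply on top. Clinical covariates (age, sex,
#' stage, T/N/M) are drawn independently of survival unless
#' \code{stage_link > 0}, in which case tumor stage is tilted toward the
#' linear predictor. Covariate draw order after the survival draws:
#' age, sex, stage latent, T, N, M.
#'
#' @param expr the expression object from \code{\link{simulateExpression}}
#'   (only used for sample bookkeeping).
#' @param truth the matching ground-truth object.
#' @param config the matching \code{\link{syntheticConfig}}.
#' @return clinical data.frame (sample, time, event, age, sex, stage,
#'   t_stage, n_stage, m_stage), tumor samples only.
#' @export
simulateSurvival <- function(expr, truth, config) {
    set.seed(config$seed + 1000003L)
    lp <- truth$per_sample_linear_predictor
    st <- names(lp)
    n <- length(st)
    h <- config$baseline_hazard * exp(lp)
    t_event <- stats::rexp(n, rate = h)
    t_cens <- if (config$censoring_rate > 0)
        stats::rexp(n, rate = config$censoring_rate) else rep(Inf, n)
    t_adm <- config$max_followup_days
    time <- pmin(t_event, t_cens, t_adm)
    event <- as.integer(t_event <= pmin(t_cens, t_adm))

    age <- pmin(90, pmax(30, round(stats::rnorm(n, 65, 10))))
    sex <- sample(c("female", "male"), n, replace = TRUE)
    latent <- stats::rnorm(n)
    if (config$stage_link > 0 && stats::sd(lp) > 0)
        latent <- latent + config$stage_link * as.vector(scale(lp))
    u <- stats::pnorm(as.vector(scale(latent)))
    stage <- cut(u, breaks = c(0, cumsum(c(0.45, 0.25, 0.2, 0.1))),
                 labels = c("I", "II", "III", "IV"), include.lowest = TRUE)
    t_stage <- sample(paste0("T", 1:4), n, replace = TRUE,
                      prob = c(0.3, 0.4, 0.2, 0.1))
    n_stage <- sample(paste0("N", 0:3), n, replace = TRUE,
                      prob = c(0.5, 0.25, 0.15, 0.1))
    m_stage <- sample(paste0("M", 0:1), n, replace = TRUE,
                      prob = c(0.85, 0.15))
    data.frame(sample = st, time = time, event = event, age = age,
               sex = sex, stage = as.character(stage), t_stage = t_stage,
               n_stage = n_stage, m_stage = m_stage,
               stringsAsFactors = FALSE)
}

#' Generate a synthetic score panel
#'
#' Per-sample tables of immune cell-type scores (per named method),
#' immune-checkpoint gene expression, and drug IC50 estimates, all
#' Gaussian around panel-specific baselines. An optional group effect
#' adds \code{shift} standard deviations to every variable for samples in
#' the "high" group.
#'
#' @param samples character vector of sample ids (or a
#'   \linkS4class{TumorNormalExperiment}, whose tumor samples are used).
#' @param seed integer seed.
#' @param groups optional data.frame (sample, group) or named character
#'   vector with "high"/"low" values.
#' @param shift planted effect size in SD units for the "high" group.
#' @param methods immune-deconvolution method labels.
#' @param cell_types immune cell types per method.
#' @param ici_genes immune-checkpoint gene panel.
#' @param drugs drug names for the IC50 table.
#' @return long-format data.frame (sample, panel_kind, variable, method,
#'   value).
#' @export
simulateScorePanel <- function(samples, seed = 1, groups = NULL, shift = 0,
                               methods = c("XCELL", "QUANTISEQ", "TIMER"),
                               cell_types = c("T cell CD4+", "Macrophage M0",
                                              "NK cell", "Neutrophil"),
                               ici_genes = c("CTLA4", "GAL9", "HAVCR2",
                                             "LAG3", "PD-1", "PD-L1",
                                             "PD-L2", "TIGIT"),
                               drugs = c("cisplatin", "docetaxel",
                                         "erlotinib", "gefitinib",
                                         "paclitaxel")) {
    if (methods::is(samples, "TumorNormalExperiment"))
        samples <- colnames(subsetByClass(samples, "tumor"))
    set.seed(as.integer(seed))
    hi <- rep(FALSE, length(samples))
    if (!is.null(groups)) {
        if (is.data.frame(groups))
            groups <- structure(groups$group, names = groups$sample)
        hi <- unname(groups[samples]) == "high"
        hi[is.na(hi)] <- FALSE
    }
    block <- function(kind, vars, meths, mu, sdv) {
        grid <- expand.grid(variable = vars, method = meths,
                            stringsAsFactors = FALSE)
        do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
            v <- stats::rnorm(length(samples), mu, sdv)
            v[hi] <- v[hi] + shift * sdv
            data.frame(sample = samples, panel_kind = kind,
                       variable = grid$variable[i], method = grid$method[i],
                       value = v, stringsAsFactors = FALSE)
        }))
    }
    rbind(
        block("immune", cell_types, methods, mu = 0, sdv = 1),
        block("ici_gene", ici_genes, NA_character_, mu = 5, sdv = 1),
        block("drug_ic50", drugs, NA_character_, mu = 3, sdv = 1))
}

#' One-call synthetic study
#'
#' Runs \code{\link{simulateExpression}}, \code{\link{simulateSurvival}}
#' and \code{\link{simulateScorePanel}} under one config.
#'
#' @param config a \code{\link{syntheticConfig}}.
#' @return list (expr, annotation, gene_set, truth, clinical, panel).
#' @export
simulateStudy <- function(config = syntheticConfig()) {
    ex <- simulateExpression(config)
    clinical <- simulateSurvival(ex$expr, ex$truth, config)
    panel <- simulateScorePanel(ex$expr, seed = config$seed + 2000003L)
    c(ex, list(clinical = clinical, panel = panel))
}
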