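# lncPairRisk

Prognostic risk models from rank-based pairs of aging-related lncRNAs.

## The problem

Expression-based survival signatures usually depend on absolute expression
levels, which makes them fragile to platform and normalisation differences
between cohorts. `lncPairRisk` implements a workflow built instead on
**relative expression ordering**: for an ordered pair of long non-coding
RNAs (A, B) and a sample *s*, the feature is the binary indicator

    alpha(A, B, s) = 1  if  x_A(s) > x_B(s),  else 0   (ties score 0)

Only the within-sample ranking enters, so alpha is invariant to any
strictly increasing per-sample transform — no cross-sample normalisation
is needed. The motivating application is lung adenocarcinoma cohorts with
matched normal tissue, a curated aging-gene panel, and survival follow-up.

The pipeline:

1. **Co-expression screen** — lncRNAs with Pearson |r| > 0.7 and p < 0.001
   against at least one aging-panel gene ("aging-related lncRNAs").
2. **Differential expression** — tumor vs normal Wilcoxon rank-sum on log2
   values, |log2FC| > 1 and BH FDR < 0.05.
3. **Pair matrix** — all C(m, 2) indicators among the differential
   lncRNAs, keeping *effective* pairs (indicator 1 in >20% and <80% of
   samples).
4. **Selection** — univariate Cox screen (Wald p < 0.05), then repeated
   cross-validated LASSO-Cox stability selection (re-randomised
   event-stratified folds; nonzero at lambda-min counts toward a pair's
   frequency; retention above a frequency threshold; one final CV-LASSO
   on the retained set).
5. **Risk model** — multivariate Cox over the selected indicators; the
   risk score is `sum_i coef_i * alpha_i(s)`.
6. **Evaluation** — time-dependent ROC (cumulative/dynamic, KM-weighted)
   at 1/3/5 years, AIC-optimal dichotomising cutoff, Kaplan–Meier +
   log-rank, clinical association and covariate-independence Cox
   analyses, and high-vs-low comparisons over immune / checkpoint-gene /
   drug-IC50 score panels.

A seeded synthetic-data module (`syntheticConfig()`, `simulateStudy()`)
generates cohorts with known ground truth — co-expression blocks, planted
differential expression, exponential proportional-hazards survival driven
by chosen signal pairs — so every stage is testable without downloads.

## Worked example

```r
library(lncPairRisk)

cfg <- syntheticConfig(n_tumor = 120, n_normal = 30, n_aging_genes = 10,
                       n_lncRNA = 40, n_linked_lncRNA = 30, n_de_up = 16,
                       n_de_down = 4, n_signal_pairs = 2,
                       true_coefficients = c(1.5, -1.0), seed = 42)
study <- simulateStudy(cfg)

pc  <- defaultPipelineConfig(n_runs = 50, retention_threshold = 5, seed = 42)
res <- runPipeline(study$expr, study$gene_set, study$clinical,
                   panel = study$panel, config = pc)

unlist(res$counts)
#>             arlncRNAs                 de_up               de_down
#>                    29                    15                     4
#>           pairs_total       pairs_effective univariate_prognostic
#>                   171                   111                    31
#>              retained              selected           model_pairs
#>                    12                    12                    12
#>                n_high                 n_low
#>                    46                    74

res$model
#> RiskModel: 12 lncRNA pairs
#>           pair    coef     hr hr_low hr_high         p
#>  LNC001|LNC002  1.3561 3.8810 1.7426  8.6434 0.0009019
#>  LNC001|LNC013  0.2966 1.3453 0.6377  2.8381 0.4361840
#>  LNC002|LNC004 -0.4136 0.6612 0.2843  1.5382 0.3369099
#>  LNC002|LNC008 -0.6857 0.5037 0.2108  1.2037 0.1228815
#>  LNC003|LNC004 -1.3155 0.2683 0.1198  0.6011 0.0013877
#>   ... 7 more pairs
```

The pipeline found 29 aging-related lncRNAs, 19 differential (15 up, 4
down), kept 111 of 171 pairs after the effective-pairing filter, and
selected a 12-pair model that contains both planted signal pairs
(`LNC001|LNC002`, true log-hazard +1.5, fitted +1.36;
`LNC003|LNC004`, true −1.0, fitted −1.32). Evaluation of the fitted
scores:

```r
res$cutoff$cutoff            # AIC-optimal cutoff: -1.203 (46 high / 74 low)
sapply(res$rocs, `[[`, "auc")
#>  d365 d1095 d1825
#> 0.836 0.912 0.937
res$km$p                     # log-rank p = 9.05e-15 (chi-square 60.1)
```

High-risk samples (score above the cutoff) die markedly faster, and the
time-dependent AUCs show the score ranks events well at every horizon —
as expected, since survival was simulated from the pair indicators.

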