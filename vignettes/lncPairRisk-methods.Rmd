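---
title: "Rank-based lncRNA pair signatures for survival risk stratification"
author: "lncPairRisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-based lncRNA pair signatures for survival risk stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem and the model

Prognostic expression signatures usually require the expression values of
different patients to live on a comparable scale, which makes them fragile
across platforms and normalisation pipelines. The workflow implemented here
sidesteps that by working with *relative expression ordering*: for an
ordered pair of long non-coding RNAs (A, B) and a sample s, the feature is

$$\alpha(A, B, s) = \mathbf{1}\{\,x_A(s) > x_B(s)\,\}$$

i.e. 1 when A is expressed above B *within* that sample. Because only the
within-sample ranking enters, $\alpha$ is invariant to any strictly
increasing per-sample transform of the expression values — library size,
log base, quantile scaling all cancel. Ties score 0; pairs are stored in a
canonical orientation (A before B lexicographically), and flipping the
orientation maps $\alpha \mapsto 1-\alpha$, which a Cox model absorbs as a
sign change of the coefficient.

The full pipeline, aimed at tumor cohorts with matched normal tissue and
survival follow-up (the motivating application is lung adenocarcinoma with
an aging-gene panel):

1. **Co-expression screen.** An lncRNA is *aging-related* if its Pearson
   correlation against at least one gene of a curated aging panel passes
   $|r| > 0.7$ and $p < 0.001$ (t-transform p on $n-2$ df). Both
   thresholds are strict inequalities.
2. **Differential expression.** Among screen survivors, a two-sided
   Wilcoxon rank-sum test of tumor vs normal on log2 values, BH-adjusted
   within that set; differential means $|\mathrm{log2FC}| > 1$ and
   FDR $< 0.05$, where log2FC is the difference of group means on the
   log2 scale.
3. **Pair construction.** All $m(m-1)/2$ pairs of the differential
   lncRNAs, then the *effective pairing* filter: keep pairs whose
   indicator is 1 in strictly more than 20% and strictly fewer than 80%
   of samples. Near-constant indicators carry no ranking information and
   destabilise the survival fits.
4. **Selection.** A univariate Cox screen (Breslow ties, Wald $p < 0.05$)
   followed by stability selection: many runs of 10-fold cross-validated
   LASSO-Cox with re-randomised, event-stratified fold assignments;
   each run counts the pairs with nonzero coefficients at the
   deviance-minimising $\lambda$; pairs selected in more than a threshold
   number of runs (default 100 of 1000) are retained, and one final
   cross-validated LASSO-Cox on the retained set picks the model pairs.
5. **Risk model.** A joint multivariate Cox fit over the selected
   indicators. The risk score of a sample is the exact linear functional
   $\sum_i \hat\beta_i\, \alpha_i(s)$, no intercept.
6. **Evaluation.** Time-dependent ROC at 1/3/5 years (365-day years),
   AIC-optimal dichotomising cutoff, Kaplan–Meier curves with the
   log-rank test, chi-square / Wilcoxon / Kruskal–Wallis clinical
   associations, univariate-plus-multivariate Cox independence analysis,
   and generic high-vs-low comparisons over immune / checkpoint-gene /
   drug-IC50 score panels.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `r_threshold`, `p_threshold` | 0.7, 0.001 | co-expression screen; strict `>` / `<` |
| `use_absolute` | TRUE | screen on \|r\|; signed r available |
| `fc_threshold`, `fdr_threshold` | 1.0, 0.05 | differential-expression call on log2 scale |
| `pair_low`, `pair_high` | 0.20, 0.80 | open interval for the effective-pair filter |
| `univariate_p` | 0.05 | Wald p for the per-pair Cox screen |
| `n_runs`, `retention_threshold` | 1000, 100 | stability runs and strict retention count |
| `folds` | 10 | CV folds per run, event-stratified |
| `horizons` | 365/1095/1825 d | ROC horizons |
| `min_followup_days` | 1 | inclusive lower bound on follow-up |
| `min_group_frac` | 0.10 | smallest group a cutoff candidate may produce |

Design choices that the source material leaves open, fixed here:

* **"Significantly elevated"** is a plain strict inequality per sample,
  not a per-sample statistical test — this is the established relative
  expression ordering construction. Ties score 0.
* **Screen sample set.** Correlations are computed on tumor samples by
  default (the signature concerns tumors); configurable to all samples.
* **Signed vs absolute r.** Absolute by default; the presence of
  down-regulated differential lncRNAs in the motivating study implies the
  absolute reading of the fold-change rule too, so both thresholds are
  absolute with signed variants available.
* **"Multiple rounds of cyclic pairing"** is implemented as one
  exhaustive enumeration of unordered pairs — the cyclic description is
  an iteration order, not a different result set.
* **$\lambda$ rule.** The deviance-minimising $\lambda$ (lambda-min) of
  `glmnet::cv.glmnet`, 10 folds stratified by event status so no fold is
  event-free. The "second cross-validation" of the original description
  is read as the final CV-LASSO on the retained set, whose surviving
  pairs feed the multivariate Cox fit that produces the reported
  coefficient table.
* **Ties in event times** use the Breslow approximation (configurable to
  Efron).
* **AIC cutoff.** Candidates are midpoints of consecutive sorted unique
  scores, guarded so each group keeps at least 10% of samples; each
  candidate is scored by the AIC of the dichotomised univariate Cox fit
  ($-2\log\hat\ell + 2$, one parameter, no intercept); exact ties break
  toward the candidate nearest the median score. Note that the
  AIC-minimal dichotomy may legitimately place the cutoff a sample or
  two away from a visually obvious gap when the boundary samples'
  survival draws are atypical.
* **Time-dependent ROC.** The cumulative/dynamic construction with
  Kaplan–Meier weighting of censored observations: sensitivity and
  specificity at horizon t are estimated from the KM survival within the
  score strata above/below each cutoff; with no censoring this reduces
  exactly to empirical case/control fractions, and the AUC (trapezoidal
  over all cutoffs) equals the concordance of (case, control-at-t)
  pairs. Values within $10^{-10}$ of 0 or 1 are snapped to the edge so
  float noise cannot push curve anchors off the ROC square.
* **Ordinal clinical coding.** Stage I–IV → 1–4, T1–T4 → 1–4, N0–N3 →
  0–3, M0/M1 → 0/1, sex female/male → 0/1; X/unknown levels become
  missing and the multivariate independence fit uses complete cases.
* **Duplicate handling.** Duplicate gene rows collapse by mean (logged);
  pairs with identical indicator vectors are deduplicated before the
  joint fit (lexicographically first kept); insufficient follow-up means
  time < 1 day by default, boundary inclusive-keep.

## What the synthetic cohorts emulate

`syntheticConfig()` defaults encode the study conditions every
acceptance-level check runs under: 400 tumor and 50 normal samples; a
50-gene aging panel driven by a 5-factor latent model; 160 lncRNAs of
which 120 are co-expressed with a panel gene at target Pearson r = 0.8
(an lncRNA is $r\,u + \sqrt{1-r^2}\,\varepsilon$ around its partner's
standardised signal, so r = 1 yields exact copies); 99 up- and 12
down-shifted differential lncRNAs at |log2FC| = 2; and exponential
proportional-hazards survival driven by 3 signal pairs with log-hazard
coefficients (1.5, −1.0, 0.8) over a baseline hazard of 5×10⁻⁴/day, with
independent exponential censoring (5×10⁻⁴/day) and administrative
censoring at 10 years — an event fraction near 0.6. Covariates (age,
sex, stage, T/N/M) are drawn independently of survival unless
`stage_link > 0`, giving covariate-independence tests a known null. The
gene-panel size and lncRNA count are desk-scale choices: large enough
that the screen, the pair filter and the selection stages all do real
work, small enough that the full pipeline runs in minutes on one CPU.

The exponential survival law is the simplest law consistent with the Cox
model and gives closed-form oracles (iid exponential times under a null
signal; event probability $h/(h+c)$ against an exponential censoring
clock). All draws flow from one seeded generator in a documented order,
so equal seeds give bit-identical cohorts.

What the generator deliberately does **not** emulate: negative-binomial
count noise, library-size and batch effects, correlated clinical
covariates, non-proportional hazards. Tests passing on these cohorts
show the machinery is correct under its stated assumptions, not that the
biological signal in any real cohort is as clean.

## Numerical choices

* Pearson p-values use the exact t-transform
  $t = r\sqrt{(n-2)/(1-r^2)}$ with $|r| \ge 1$ mapped to $p = 0$;
  zero-variance vectors are skipped with a warning.
* Wilcoxon tests use exact enumeration for small tie-free groups and the
  normal approximation with continuity correction otherwise
  (`stats::wilcox.test` rules).
* Univariate Cox screens run through `survival::coxph.fit` (Newton on
  the Breslow partial likelihood); fits with unbounded coefficients
  (monotone likelihood / perfect separation: $|\hat\beta| > 15$ or
  SE > 50) are excluded with a warning, as are constant pairs.
* `glmnet` defaults govern the LASSO path (100 $\lambda$ values,
  coordinate-descent tolerance 10⁻⁷); stability runs use master seed + run
  index, so a fixed master seed reproduces the whole frequency table.
  The path is truncated once `dfmax = 100` pairs have entered — a pure
  speed guard: whenever the cross-validated minimum lands on the
  truncated end, that run is automatically redone with the full path, so
  the $\lambda$-min rule is exact.
* Wald 95% CIs use $\pm 1.959964\,\mathrm{SE}$; hazard ratios are
  `exp(coef)` to machine precision before any printing.

## Problem sizes used by the shipped checks

The test suite exercises every stage at small scale (tens to hundreds of
samples) plus one pipeline run at the full study conditions with the
stability stage at 200 runs and a 10%-of-runs retention threshold — the
frequency criterion scales with the run count, and 200 re-randomised
fold draws already give stable frequencies on a fixed dataset.
Coefficient-recovery coverage is measured over 20 seeded cohorts by
fitting the final multivariate Cox on the planted signal pairs (whose
recovery by the selection stages is checked separately), and
differential-expression recovery over the same 20 seeds. Calibration
checks use 2000 uncensored samples for the null AUC, 100 replicates for
the null false-discovery fraction, and 200 replicates for null p-value
uniformity.

## Known limitations

* Stability frequencies are computed over fold re-randomisations of one
  dataset, not over data resamples; a noise pair with a chance
  association in that dataset can be selected in many runs. This matches
  the original procedure's description, but means retention under the
  null is dataset-dependent rather than uniformly rare.
* Pair indicators are heavily correlated when pairs share a member, and
  L1 selection keeps one representative of a correlated group: a true
  signal pair can be crowded out of every run by a near-duplicate
  surrogate pair, in which case the model carries the signal through the
  surrogate rather than the planted pair itself. Selection frequencies
  identify *a* sparse representation, not the unique causal pairs.
* The cumulative/dynamic KM-weighted ROC estimator can be locally
  non-monotone in small samples; the reported AUC integrates the curve
  as estimated.
* The multivariate Cox coefficient table is conditional on the selection
  path; no post-selection inference correction is applied (none is part
  of the emulated workflow).
* Immune-infiltration scores and drug IC50 values are consumed as input
  tables; their computation is out of scope.
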