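---
title: "Methods: signature scores, survival comparison, and the synthetic mixture cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signature scores, survival comparison, and the synthetic mixture cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cafindex)
```

## The problem

Bulk tumor expression profiles are mixtures. The non-malignant stroma —
cancer-associated fibroblasts (CAFs) in particular — expresses many of
the canonical mesenchymal genes (FN1, VIM, the SNAIL/ZEB/TWIST factors'
targets), so a bulk "EMT score" cannot separate tumor cells that have
undergone an epithelial–mesenchymal transition from tumors that are
simply stroma-rich. When the stroma is what drives outcome, a score that
reads stromal abundance directly should predict survival better than a
score diluted by tumor-intrinsic EMT variation. `cafindex` implements
both kinds of score and the survival framework to compare them.

## The scores

All scores operate on log2 expression (`expr_matrix` with
`scale = "log2"`; linear matrices must pass through `to_log2()`
explicitly — double log-transformation is an error, never a silent
no-op).

**14-gene EMT score** (`score_emt_salt()`): the sum of nine mesenchymal
gene values minus the sum of five epithelial gene values per sample.
No z-scoring or weighting is applied; the score is a raw log2 sum, so
adding a constant *c* to every value shifts it by (9 − 5)·*c* (a tested
invariant). The bundled panel carries the canonical markers: mesenchymal
FN1, VIM, ZEB1/2, SNAI1/2, TWIST1/2 plus CDH2 (the cadherin-switch
partner), epithelial CDH1, CLDN4, CLDN7 plus EPCAM and KRT8 (the
standard epithelial surface/keratin markers). The panel file
(`inst/extdata/panels/emt_salt14.tsv`) is deliberately editable: EMT
panels differ between studies, and the count validation (9 + 5) only
binds the default panel name. Panel genes missing from a cohort are
omitted from their sum and reported in `genes_missing` — the same
handling older arrays require when, e.g., TWIST2 has no probe.

**4-gene CAF index** (`score_caf_index()`): the summed log2 expression
of FN1, TGFB2, TGFBR2 and TGFBI. The sum-of-logs construction mirrors
the EMT score so that the two are directly comparable; it is *not*
log2-of-sum. FN1 is the only gene the two default panels share.

**76-gene weighted EMT score** (`score_76gs()`): per cohort, each panel
gene's weight is its Pearson correlation with CDH1 across samples
(CDH1's own weight is exactly 1); the score is the weighted sum of
per-gene mean-centered values. Weights are cohort-dependent by design —
they are recomputed for every matrix, never stored in the panel.
Mean-centering is per gene across the cohort's samples (the natural
reading of "mean-centered"; a global grand-mean alternative would break
the tested invariance to per-gene constant shifts). Because epithelial
genes correlate positively and mesenchymal genes negatively with CDH1,
positive scores mean epithelial — the opposite sign convention to the
14-gene score, and the two anti-correlate on any cohort with a real
epithelial–mesenchymal axis (a tested property). Genes with zero
variance have undefined correlations and receive weight 0, logged. The
bundled 76-gene list is a curated set of canonical epithelial and
mesenchymal markers; any published 76-gene list can be substituted via
`load_panel()` without touching code. Pearson (not Spearman) is used
for the weights, matching standard practice for this score family.

Gene matching is case-insensitive with exact-case preference, because
public platforms mix symbol cases; no alias or ortholog mapping is
attempted — panels must use the cohort's symbol namespace.

## Survival machinery

The package implements its own survival stack rather than delegating,
so that every formula is visible and testable:

- `km_estimate()`: the product-limit estimator over distinct event
  times; a subject censored exactly at an event time is at risk for
  that event (standard convention).
- `logrank_test()`: two-group log-rank with the hypergeometric variance
  (including the `(n_i − d_i)/(n_i − 1)` tie correction); chi-square
  with 1 df.
- `cox_fit()`: Newton–Raphson from β = 0 on the partial likelihood with
  the **Efron** approximation for ties (the default of mainstream
  survival software, and the better approximation when ties are
  frequent; Breslow is available). Step-halving guards every iteration
  — a step is only accepted if the partial likelihood does not
  decrease. Convergence is declared at gradient max-norm below 1e-9
  within 50 iterations. Standard errors come from the inverse observed
  information; intervals and p-values are Wald on the hazard-ratio
  scale (matching the "HR; 95% CI; p" reporting convention).
  Divergence of |β| beyond 15 is flagged as monotone likelihood
  (perfect separation) with `converged = FALSE`; constant covariates
  are an error naming the column.

The test suite pins these implementations to independent oracles: hand
product-limit and O/E/V tabulations, a dense grid search over the naive
partial likelihood, the classical identity between the Cox score test
at β = 0 and the log-rank statistic (exact in the tie-free case), the
reference `survival::coxph()` on random datasets (agreement to 1e-6 —
used only as a test oracle, never at run time), and a 2000-replicate
null simulation calibrating the log-rank type-I error to 0.05 ± 0.01.

## The comparison pipeline

`run_comparison()` fixes the analysis order: apply exclusions once,
compute all scores on the surviving samples, dichotomize each at the
cohort **median** (high = strictly above; ties go to low — with many
tied scores this makes the high group the smaller one, which is the
conservative direction), then per score a Kaplan–Meier pair and
log-rank test, one univariate Cox model per covariate/score, and one
multivariate model with everything jointly. Scores enter the Cox models
as high/low indicators by default — hazard ratios in the tens, as seen
for small dichotomized cohorts, are only interpretable on that scale —
with `continuous_scores = TRUE` preserving the alternative. No multiple
-testing correction is applied: the report shows raw per-term p-values,
and says so here rather than adjusting silently. Exclusions (e.g.
treatment-related deaths) are always caller-supplied configuration,
never hard-coded sample ids. The whole report is a pure function of its
inputs (tested by exact identity of repeated runs).

`correlate_purity()` relates a score to an exome-style tumor-content
estimate by Pearson correlation; a stromal score should correlate
negatively, since purity is the complement of stromal fraction.
`groupwise_index_summary()` ranks groups (e.g. primary sites) by median
score for box-plot-style comparisons.

## The synthetic mixture cohort

`generate_cohort()` draws, per sample *i*:

1. stromal fraction `f_i ~ Beta(2, 6)` (mean 0.25; the spread covers
   the roughly 10–35% stromal read fractions xenograft studies report);
2. a tumor-intrinsic EMT state `u_i ~ N(0, 1)` in log2 units,
   independent of survival;
3. linear expression `x_gi = ((1 − f_i)·T_gi + f_i·S_g)·ε`, with
   `ε ~ lognormal(0, 0.3)` (multiplicative noise on the linear scale is
   additive Gaussian on log2, microarray-like). The stroma/tumor ratio
   `S_g/T_g` is 8 for the four CAF-index genes, 3 for the other
   mesenchymal panel genes, 0.2 for epithelial genes and 1 for the 200
   background genes; the tumor profile of EMT-panel genes is modulated
   by `2^(±u_i)` (up for mesenchymal, down for epithelial);
4. an event time from a proportional-hazards Weibull (shape 1 =
   exponential by default) with baseline rate 0.01/month and log-hazard
   `3·f_i`;
5. administrative censoring at 60 months plus 10% uniform dropout;
6. `purity_i = clip(1 − f_i + N(0, 0.05), 0, 1)`.

The draw order (f, EMT state, expression, survival, censoring, purity)
is fixed, so a seed reproduces a cohort byte for byte.

The tumor-intrinsic EMT state is the generator's essential piece of
realism: without it the bulk EMT score would be almost as pure a
readout of `f` as the CAF index, and the comparison would have no
structure to detect. Its default spread (sd 1 on log2) corresponds to
the 2–22× fold-change range EMT genes show across real carcinoma cell
lines, and it loads on 13 of the 14 EMT-panel genes but only on FN1
among the four CAF genes — so the CAF index stays a clean stromal
readout while the EMT score is genuinely confounded. With defaults, the
CAF index recovers the true stromal fraction at Spearman ≈ 0.89, and
its dichotomy beats the EMT dichotomy's log-rank statistic in well over
90% of replicate cohorts.

What the generator does **not** emulate: multiple stromal cell types
(immune infiltrate is absorbed into a single CAF-like profile),
count-based noise (no mean–variance relationship), batch effects,
non-proportional hazards, and correlated gene–gene structure beyond the
two latent factors. Passing tests therefore demonstrate the
correctness and calibration of the machinery on data with the assumed
mixture structure — not that any particular real cohort satisfies that
structure.

## Problem sizes and numerical choices

The shipped tests use cohorts of 40–200 samples (400 for hazard-ratio
recovery), 50 replicates for the headline win-rate, and 2000
simulations for the type-I error — sizes at which every stochastic
check has comfortable margin while the whole suite runs in seconds.
Dichotomization requires both groups non-empty and errors on constant
scores. `read_expression()` infers scale when unhinted (max < 30 ⇒
log2: microarray/log-TPM values never reach 30, raw counts/TPM always
do) and never transforms silently. Duplicate gene symbols collapse by
per-sample mean (symmetric, scale-robust on log2 data); rows with
missing values are dropped, not imputed, since imputation would leak
into scores invisibly. The log2 pseudocount defaults to 1 so zero maps
to zero.

## Known limitations

- The Cox implementation covers plain right-censored models only: no
  strata, time-varying covariates, robust variance, or penalization.
- Wald inference can be poor at very few events (the familiar wide CIs
  of small dichotomized cohorts); likelihood-ratio intervals are not
  provided.
- Nearly collinear covariates (e.g. the two EMT scores in one model)
  yield unstable joint estimates, as in any unpenalized Cox fit.
- Purity is treated as given; the package does not estimate tumor
  content from genomic data.
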