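# cafindex

Transcriptome-based prognostic scoring for bulk tumor expression data,
centered on the question of what a bulk "EMT score" actually measures.
In many solid tumors the mesenchymal expression phenotype predicts poor
survival, but the stromal compartment — above all cancer-associated
fibroblasts (CAFs) — expresses many canonical mesenchymal genes, so a
bulk EMT score conflates tumor-intrinsic epithelial–mesenchymal
transition with stromal infiltration. `cafindex` implements three
per-sample scores and the survival framework to compare them head to
head:

- **EMT score (14-gene)** — for sample *s* with log2 expression *x*:

  `EMT_s = Σ_{g ∈ mesenchymal(9)} x_gs − Σ_{g ∈ epithelial(5)} x_gs`

- **CAF index (4-gene)** — a proxy for CAF abundance:

  `CAF_s = x_FN1,s + x_TGFB2,s + x_TGFBR2,s + x_TGFBI,s`

- **76-gene weighted EMT score** — per cohort, each panel gene *g* gets
  weight `w_g = cor(x_g·, x_CDH1·)` (Pearson, across samples) and

  `S76_s = Σ_g w_g (x_gs − mean(x_g·))`

  so positive values indicate an epithelial, negative a mesenchymal
  phenotype (it anti-correlates with the 14-gene score by
  construction).

Each score is dichotomized at the cohort median (high = strictly above)
and assessed with from-scratch survival machinery: Kaplan–Meier
product-limit curves, the two-group log-rank test with hypergeometric
variance, and Cox proportional hazards `h(t|x) = h0(t)·exp(βᵀx)` fitted
by Newton–Raphson on the partial likelihood with the Efron tie
approximation (Wald SEs, CIs and p-values). A synthetic tumor/stroma
mixture cohort generator with known ground truth makes the whole
pipeline testable offline.

Intended users: computational biologists evaluating stromal/EMT
signatures as survival biomarkers, and anyone needing a small,
dependency-light, fully testable KM/log-rank/Cox stack in R.

## Worked example

```r
library(cafindex)

# a synthetic cohort: 200 bulk samples, each a tumor/stroma mixture with
# latent stromal fraction f; hazard of death increases with f
cohort <- generate_cohort(synthetic_cohort_config(seed = 1))
expr <- to_log2(cohort$expression)

report <- run_comparison(expr, cohort$clinical, with_76gs = TRUE)
report
#> <comparison_report> n = 200 (147 events), 0 exclusion(s)
#>   emt_salt   log-rank chi-square = 5.033, p = 0.02487
#>   caf_index  log-rank chi-square = 16.99, p = 3.764e-05
#>   emt_76gs   log-rank chi-square = 4.355, p = 0.0369
#> multivariate Cox:
#> <cox_fit> n = 200, events = 147, ties = efron, converged (5 iter)
#>       term   beta     se    hr ci_low ci_high    p_wald
#>   emt_salt 2.0380 1.6750 7.676 0.2879 204.700 0.2237000
#>  caf_index 0.6499 0.1812 1.915 1.3430   2.732 0.0003357
#>   emt_76gs 1.9120 1.6750 6.765 0.2537 180.400 0.2538000
```

Every dichotomy separates survival on its own, but the CAF index
carries by far the largest log-rank statistic (17.0 vs 5.0 and 4.4),
and in the joint Cox model it is the only covariate that stays
significant (HR 1.92, 95% CI 1.34–2.73, p < 0.001). The two EMT scores
are nearly collinear (they measure the same axis with opposite signs),
so their joint estimates are wide and neither is significant — high
bulk "EMT" is largely a readout of stromal content here, and the stroma
is what drives the hazard. The index also tracks the simulated
exome-style tumor content negatively:

```r
caf <- score_caf_index(expr)
correlate_purity(caf, setNames(cohort$truth$purity, cohort$truth$sample_id))
#> $r
#> [1] -0.8416679
```

Real cohorts enter through `read_expression()` (plain or
GEO-series-matrix-style TSV) and `read_clinical()`; the bundled gene
panels live in `inst/extdata/panels/` and can be replaced via
`load_panel()`.

## Command line

A thin launcher wraps the same functions:

```sh
scorekit=$(Rscript -e 'cat(system.file("exec","scorekit",package="cafindex"))')
Rscript "$scorekit" simulate --seed 1 --out-dir sim/
Rscript "$scorekit" score   --expression sim/expression.tsv --panel caf4
Rscript "$scorekit" compare --expression sim/expression.tsv \
    --clinical sim/clinical.tsv --out-dir report/
```

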