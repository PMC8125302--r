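# senopanel

Blood immunosenescence biomarker panels for age, frailty and tumor immune
infiltrate classification in early luminal breast cancer cohorts.

## The problem

Treatment decisions for older breast cancer patients hinge on biological
age and frailty, which the G8 geriatric screening score (0–17; ≤ 14 flags
vulnerability) captures only coarsely. This package implements a complete
screening pipeline that asks whether circulating immune/senescence
biomarkers — plasma cytokines and immune checkpoint proteins, miRNAs,
T-cell *P16^INK4a^*, PBMC subset frequencies — can classify patients into
age groups (35–45/55–65 vs ≥ 70 years), G8-based frailty groups (fit
G8 > 14 vs frailer G8 ≤ 14), and tumor immune infiltrate categories (sTIL
%, CD3/CD8 densities in the whole tumor and invasive front).

## The method

1. **Standardization** — every biomarker is z-scored over its observed
   entries (sample SD, n − 1), so heterogeneous units become comparable.
2. **Single-biomarker ranking** — per contrast, each biomarker gets an
   oriented ROC-AUC (Mann–Whitney identity, `max(AUC, 1 − AUC)`), a
   two-sided Wilcoxon rank-sum p (exact on small tie-free groups), and a
   standardized log fold-change (difference of standardized group means,
   `log FC = A − B`). These become ranks, combined as
   `composite = 2·rank_AUC + rank_p + rank_FC` (AUC weighted double);
   three-class infiltrate contrasts are ranked one-vs-rest per category.
3. **Exhaustive panel search** — every 1-, 2- and 3-biomarker panel is
   fitted with an internally implemented linear discriminant classifier
   (shared covariance, empirical priors,
   `δ_c(x) = xᵀΣ⁻¹μ_c − ½μ_cᵀΣ⁻¹μ_c + log π_c`, posteriors by softmax) on
   its complete-case patients, and scored by resubstitution **accuracy**
   (% argmax-correct) and **loss** `L = 100·mean(1 − P(true class | x))`
   (mean residual misclassification probability). Panels are ranked by
   accuracy, then loss. No cross-validation is performed — by design —
   and the optimism this produces is measured, not assumed (see the
   acceptance checks).
4. **Covariate augmentation** — age, breast-cancer parameters (tumor
   size, grade, nodal stage) or frailty can be appended to any panel as
   extra z-scored classifier features.
5. **Infiltrate categorization** — sTILs at fixed cutpoints (< 10% low,
   10–40% intermediate, > 40% high); CD3/CD8 densities at cohort
   quartiles (type-7; lower quartile low, upper quartile high).
6. **Synthetic cohorts** — a tested generator reproduces the study
   structure (34 + 31 patients, 19/10/2 frailty split, ~100 biomarkers in
   four assay families, block-wise missingness, planted effects of size d
   with expected AUC Φ(d/√2), biomarkers tied monotonically to
   infiltrate variables), so the whole pipeline validates against known
   ground truth without any patient data.

## Worked example

```r
library(senopanel)

cfg <- synthetic_config(
  planted = data.frame(index = c(5, 35, 65), contrast = "age", d = 1.5),
  seed = 7)
g <- generate_cohort(cfg)

sr <- run_search(g$cohort, g$matrix, contrast = "age", k_list = 3)
head(sr$top[, c("rank", "panel", "n", "accuracy", "loss")])
```

Output (the planted biomarkers are `plasma_05`, `mirna_07`, `pbmc_16`):

```
  rank                          panel  n accuracy      loss
1    1 mirna_07 + pbmc_16 + tcell_p16 38 97.36842  5.959065
2    2 mirna_07 + pbmc_39 + tcell_p16 38 97.36842 11.812975
3    3 mirna_07 + pbmc_17 + tcell_p16 38 97.36842 13.777157
```

Each row is one of the 161,700 three-biomarker panels: `n` is the number
of patients with all three assays observed (38 here, because the
flow-cytometry and P16 blocks are each missing for a subset of the 65
patients and this panel needs both), `accuracy` the percentage of those
patients the panel classifies into the correct age group on
resubstitution, and `loss` the mean posterior probability the model left
on the wrong age group. The top panel contains two of the three planted
biomarkers; ranking individual biomarkers on the same cohort puts all
three planted ones first:

```r
rb <- rank_biomarkers(zscore(g$matrix), contrast_labels(g$cohort, "age"))
head(rb[, c("name", "auc", "p_value", "log_fc", "final_rank")], 3)
#>        name       auc      p_value    log_fc final_rank
#> 1  mirna_07 0.8709677 2.915286e-07 1.2686266          1
#> 2   pbmc_16 0.8592593 3.437141e-06 1.2529579          2
#> 3 plasma_05 0.8168880 1.185691e-05 0.9805966          3
```

The `analysis/` directory holds the full narrative workflow as numbered
drivers: `01_simulate_cohort.R` (reference cohort), `02_rank_biomarkers.R`
(per-contrast rankings), `03_search_panels.R` (age/frailty top-10 panel
tables), `04_infiltrate_panels.R` (infiltrate categorization and
covariate-augmented three-class searches), `05_projections.R` (LD1
density-plot coordinates and LD1/LD2 score coordinates with 66%/95%
confidence ellipsoids). Each writes its tables under `results/`.

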