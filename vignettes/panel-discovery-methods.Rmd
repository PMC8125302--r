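---
title: "Blood biomarker panel discovery: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Blood biomarker panel discovery: models, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(senopanel)
```

## The problem

Older patients with early luminal breast cancer differ widely in biological
age: some tolerate full treatment, others are vulnerable to it. Clinical
frailty is screened with the G8 questionnaire (0–17; a score of 14 or lower
flags vulnerability), but G8 is a coarse surrogate for a full geriatric
assessment. The hypothesis behind this package is that the blood
immune/senescence profile — plasma cytokines and checkpoint proteins,
circulating miRNAs, T-cell *P16^INK4a^* expression, PBMC subset
frequencies — carries enough signal to classify patients by chronological
age group, by G8-based frailty, and perhaps by the level of immune
infiltration of their tumor.

`senopanel` implements the analysis machinery end to end: standardize a
heterogeneous biomarker matrix, rank individual biomarkers per contrast,
exhaustively score every 1–3 biomarker panel with a linear discriminant
classifier, categorize tumor infiltrates, and export plot-ready
discriminant coordinates. Because no patient-level dataset is distributed
in machine-readable form, the package also ships a synthetic cohort
generator that reproduces the *structure* of such a study, so that every
stage is testable against known ground truth.

## Single-biomarker scoring

Biomarkers arrive in incompatible units (pg/mL, Cq-like cycles, relative
expression, percentages), so each biomarker is z-scored over its observed
entries with the sample SD (n − 1). Constant biomarkers are flagged and set
to zero rather than dropped, so downstream bookkeeping stays aligned.

For a two-group contrast each biomarker gets three statistics:

* **ROC-AUC** via the Mann–Whitney identity,
  AUC = [#(a > b) + ½·#(a = b)] / (n_A n_B) over all between-class pairs,
  computed from midranks. Ranking uses the *oriented* AUC,
  max(AUC, 1 − AUC), because a biomarker elevated in either group is
  equally useful; the direction is kept in the signed fold-change.
* **Wilcoxon rank-sum p** (two-sided). The exact distribution is used when
  both groups have ≤ 8 observations and the pooled values are tie-free;
  otherwise the normal approximation with tie and continuity corrections.
  No multiple-testing correction is applied — the ranking is exploratory
  screening, not inference.
* **Standardized log fold-change**: the difference of standardized group
  means, A − B, with A the group of interest (older, frailer, or the
  infiltrate category under test). On a standardized/log-like scale the
  ratio of groups becomes a subtraction; z-scores can be negative, so a
  literal ratio would be ill-defined, and the mean difference is the
  coherent reading of "log FC = A − B" for standardized data.

Each statistic becomes a rank (average ranks on ties) and the composite is
`2·rank_AUC + rank_p + rank_FC` — the AUC deliberately weighted double.
Final ordering breaks composite ties by oriented AUC, then by name, so the
output is a reproducible total order. Three-class infiltrate contrasts are
ranked one-vs-rest per category, since the informative biomarkers for
*high* infiltration need not be those for *low*.

## The panel classifier

Panels are scored with linear discriminant analysis implemented in the
package (the compiled kernel and the reference R path are cross-checked
against each other and against an independent implementation in the test
suite): Gaussian classes with a shared covariance, estimated as the pooled
within-class covariance with the n − k denominator, empirical class
priors, and discriminant scores

δ_c(x) = xᵀ Σ⁻¹ μ_c − ½ μ_cᵀ Σ⁻¹ μ_c + log π_c,

with posteriors the softmax of δ. The number of discriminant axes is
min(k − 1, p): one for binary contrasts (density plots over LD1), two for
the three-class infiltrate contrasts (LD1/LD2 score plots with 66% and 95%
confidence ellipsoids; the squared radii are the χ²₂ quantiles 2.158 and
5.991 times the eigenvalues of the per-group covariance of the LD
coordinates).

Two metrics summarize a fitted panel:

* **accuracy** = 100 × fraction of samples whose posterior argmax equals
  the true class;
* **loss (L)** = 100 × mean over samples of (1 − posterior of the true
  class), the mean residual probability of misclassification. L is a
  *mean*, not a sum, so it lives on a fixed 0–100% scale regardless of the
  panel's complete-case size. A panel can be 100% accurate with L well
  above zero — every sample on the right side of the boundary but none
  with a confident posterior — and the tests exhibit exactly this pattern.

Degenerate pooled covariances (duplicated or constant features) are
handled by an automatic ridge, ε = 10⁻⁶·trace(Σ)/p, with a warning;
posterior ties at the argmax resolve to the first class in label order.
Both choices are purely for determinism on pathological panels.

## Exhaustive panel search

All C(p, k) panels for k ∈ {1, 2, 3} are enumerated in lexicographic
order. Each panel is evaluated on its **complete cases**: patients with a
defined label and all panel biomarkers observed. No imputation is done —
this is what makes the reported per-panel N vary when assays are missing
block-wise, and it is the reason the generator's missingness is block-wise
too. Panels leaving any class below `min_per_class = 2` complete cases are
reported as unevaluable rather than silently dropped.

Panels are ranked by accuracy (descending), then loss (ascending), then
panel name. Evaluation is resubstitution — the model is scored on the
patients it was fitted on, with no cross-validation, matching the
exploratory design this package reimplements. The consequence is
quantified rather than hidden: under a global null (no planted effects,
29 patients, frailty contrast), the best of all three-biomarker panels
from 100 candidate biomarkers typically reaches > 90% resubstitution
accuracy (the acceptance checks measure this across 100 simulated
cohorts). Top-ranked panels are therefore hypotheses for validation, not
validated classifiers.

Clinical covariates (age; tumor size, grade as 1–3, nodal stage as pN0–pN3
encoded 0–3; frailty as a binary indicator) can be appended to any panel
as additional z-scored classifier features. The augmented model is
evaluated on the base panel's complete-case set, since the clinical
variables are available for essentially all patients; patients missing a
covariate are dropped with a message.

## Infiltrate categorization

Stromal TIL percentages use fixed cutpoints: < 10% low, 10–40%
intermediate, > 40% high. The boundary values 10 and 40 go to
*intermediate* because the outer categories are defined by strict
inequalities. CD3/CD8 densities are cut at the cohort's 25th and 75th
percentiles (type-7, linear-interpolation quantiles; the quantile
algorithm is a convention choice): v ≤ q1 low, v ≥ q3 high. Quartiles are
computed **once on the whole cohort** and then applied per patient;
recomputing them on a subset would move the cutpoints, so the API returns
the cutoffs alongside the labels and callers subset afterwards. On
tie-free data this yields the intended ≈ 25 / 50 / 25% split; with heavy
ties it degenerates (all values equal collapses to *low*, with a message).

## The synthetic cohort generator

The generator is a first-class, tested module, not a fixture. Its defaults
are the study conditions the pipeline assumes: 34 younger + 31 older
patients; 19 fit, 10 frailer and 2 unscored among the older; ~100
biomarkers split into four assay families simulated on their natural
scales (log-normal plasma proteins, Gaussian qPCR-like miRNAs, log2-normal
T-cell *P16^INK4a^*, logit-normal PBMC percentages); the flow-cytometry
block missing for ~12% of patients and the P16 assay for ~30% (so that
multi-assay panels show the varying complete-case N the analysis must
handle); three patients without tumor tissue.

Effects are planted on the latent standard-normal scale: a biomarker with
effect size d has its group-of-interest mean shifted by d pooled SDs, and
since every family transform is strictly increasing, the observable
two-group AUC is exactly Φ(d/√2) in expectation. (This is why PBMC
percentages are bounded by a logistic transform rather than clipping:
clipping would create ties and break the closed form.) The same latent
trick ties biomarkers monotonically to infiltrate variables at a chosen
correlation. Within-family equicorrelation ρ is available to approximate
the strong nesting of PBMC subset definitions; the default is independent
biomarkers.

What the generator does **not** emulate: real between-assay correlation
structure, heavy-tailed measurement error, batch effects, informative
missingness, or the exact subset arithmetic of nested flow gates. Tests
passing on synthetic cohorts therefore validate the *machinery* —
statistics, search, ranking, bookkeeping — not the biological claims of
any particular cohort.

## Numerical and validation choices

* Wilcoxon p-values delegate to R's `wilcox.test` with the exactness rule
  above; the test suite validates them against an independent enumeration
  of all label assignments for every split of n ≤ 8 tie-free values.
* ROC-AUC is validated against brute-force between-class pair counting on
  thousands of random vectors with and without ties.
* The discriminant classifier is validated three ways: against the
  shared-covariance Gaussian density quotient (agreement to 1e-9), against
  an established reference implementation (labels identical, posteriors to
  1e-6, on 200 random instances), and the compiled search kernel against
  the pure-R path on random panels including missing-data and three-class
  cases.
* The "uninformative model has L = 50%" contract is checked on the
  out-of-sample loss (fit on 200 null samples, evaluate on 200 fresh ones,
  200 simulations): the resubstitution estimate of L is biased below 50 by
  O(1/n) — the same order as its own simulation SD, at every n — so only
  the out-of-sample loss is an unbiased read of the model property. The
  in-sample optimism itself is asserted separately.
* Planted-panel recovery is run at the study's cohort size (34 + 31, 100
  biomarkers, three planted age-effect biomarkers at d = 1.5, i.e. an
  expected per-biomarker AUC of Φ(1.5/√2) ≈ 0.86, across 20 seeds), and
  the null-optimism experiment across 100 seeds; both finish in minutes
  because the exhaustive search (161,700 panels per seed) runs in the
  compiled kernel.
* End-to-end determinism (identical config + seed ⇒ byte-identical ranked
  tables) is asserted at the file level.

## Known limitations

Resubstitution metrics are optimistic and panel rankings are unstable at
these sample sizes; the package reports them faithfully because the
procedure it implements is defined that way, and it documents the optimism
with a measured null experiment instead of a disclaimer. The composite
rank treats the three criteria as exchangeable ranks (beyond the double
AUC weight), ignoring their correlation. Covariate-augmented panels reuse
the base panel's complete-case set rather than re-filtering. One-vs-rest
ranking for three-class contrasts does not use the three-class LDA's own
feature importances.
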