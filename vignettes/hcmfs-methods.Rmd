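---
title: "HC-MFS: methods, design choices and what the tests show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{HC-MFS: methods, design choices and what the tests show}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcmfs)
```

## The selection model

HC-MFS targets two-class tabular cohorts in which features are both
redundant (collinear blocks of clinical measurements) and of very unequal
relevance. It interleaves a redundancy view and a relevance view:

* **Redundancy** is captured by Ward agglomerative clustering of the
  *features*. Every feature column is z-scored (population SD) and viewed
  as a vector over samples, so the squared Euclidean distance between two
  features is `2 n (1 − r)` with `r` their Pearson correlation, and
  Ward's minimum-variance objective is well defined. This is the only
  representation under which Ward's criterion has its textbook meaning,
  which is why it is the default; a correlation-type distance would change
  heights but not the qualitative partition on standardized data.
* **Relevance** is the Fisher score
  `FS = Σ_c n_c (μ_c − μ)² / Σ_c n_c σ_c²` with *population* class
  variances. The 1/n convention is a deliberate, documented constant: it
  makes small worked examples exact (e.g. `x = 0..5` against balanced
  labels gives 13.5/4 = 3.375) and differs from the 1/(n−1) convention
  only by a label-independent factor, so rankings are unaffected.
* **Seeding** thresholds each feature against the *mean* Fisher score of
  its own cluster, strictly. Strictness matters: a cluster whose scores
  are all equal contributes nothing, and the seed is exactly the set of
  locally outstanding features. One threshold per redundancy class keeps
  a strong but redundant block from flooding the seed.
* **Wrapper refinement** runs one forward and one backward greedy pass,
  both scored by stratified k-fold cross-validated accuracy of a
  configurable classifier, both visiting every candidate exactly once.

### Wrapper-search conventions

Several details are genuinely open design choices; the package fixes them
as follows and exposes none of them as silent behavior:

* **Candidate order** is descending Fisher score for the forward pass and
  ascending for the backward pass (ties broken by column order). A
  relevance-driven order makes the single greedy pass spend its budget on
  the most promising candidates first; the order is recorded in the
  configuration.
* **Acceptance rules**: forward additions require a *strict* CV-accuracy
  increase; backward removals require *no decrease*. The asymmetry is the
  parsimony direction in both cases — an addition that buys nothing is
  rejected, a removal that costs nothing is taken — and it prevents
  accept/reject oscillation on exact ties.
* **The backward pass starts from the full feature set**, not from the
  seed; seed members are protected and never removed. Starting from the
  full set is the only reading under which a backward winner can be
  *larger* than the seed, which is a state this pipeline must be able to
  reach (and does reach in the worked example: a 15-feature backward
  winner around a 7-feature seed).
* **The fold partition is frozen once per search** (stratified, derived
  from the run seed), so every accuracy comparison within a search is
  paired. Re-randomizing folds per candidate would add noise exactly
  where the greedy rule is most sensitive.
* **Final comparison**: higher final accuracy wins; an exact tie goes to
  the smaller subset; a tie in both goes to forward.
* Numeric features are standardized *inside each training fold* (mean and
  population SD of the training portion applied to the held-out fold).
  Whole-table standardization is available for exploratory reports
  (`standardize_table()`, the `IMV+SS` variant), but model evaluation
  never lets held-out rows influence scaling.

### Default parameters

| Parameter | Default | Why |
|---|---|---|
| `k_classes` | 3 | the cohort's feature dendrogram reading (season/cholesterol, age/red-cell, platelets); `suggest_k()` offers a silhouette-based hint but never overrides an explicit `k` |
| `cv_folds` | 5 | the evaluation protocol used throughout the benchmark |
| wrapper classifier | unpenalized logistic regression | deterministic, fast, and a reasonable linear baseline for ~20-feature clinical tables; any `model_config()` can be substituted |
| Relief-F `k` | 10 (capped at class size − 1 for the ranking default) | standard Kononenko setting; numeric differences range-normalized |
| MI bins | 10 equal-frequency | a plug-in estimate on a continuous feature needs multi-bin discretization; equal-frequency bins keep marginal bin mass flat |
| outlier rule | \|z\| > 3, mean substitution | conventional cut; substitution uses the mean of the *unflagged* cells so a flagged cell cannot drag its own replacement |
| sparse-row budget | > 5 missing cells per row | the cohort's stated entry-removal rule |

## The synthetic cohort generator

`table1_spec()` encodes the AF cohort's published per-group summaries:
17 numeric features as `mean ± SD` per group, season as a 4-level
categorical with the printed per-group proportions (encoded ordinally 1–4
downstream, matching the source's treatment of season as a single
feature), and diabetes/hypertension as binaries. `generate_cohort()`
draws Gaussian marginals per group and couples features that share a
correlation block through a Gaussian copula with an equicorrelated latent
(common factor), so the printed marginal moments are preserved exactly
while the block structure reproduces the three-cluster dendrogram
topology. Default within-block correlation is 0.5 — moderate clinical
collinearity; the clustering-recovery checks use 0.8, the condition under
which the three-class topology is asserted.

Two deliberate deviations from the printed table:

* the AF-group platelet-crit SD is taken as **0.069**, reading the
  printed 0.69 as a misplaced decimal (0.69 would be 3.6× the mean and
  ~10× the control group's SD of 0.08);
* **CRP has no floor at zero.** Its printed SD (55.00) is about twice its
  mean (27.74); truncating a Gaussian with that shape at zero would
  inflate the mean by roughly half an SD and the generator could no
  longer reproduce the printed moments. Occasional negative CRP draws
  are an accepted artifact of the Gaussian marginal. All other
  concentrations and counts are floored at zero by resampling (not
  clipping, which would create a point mass at the bound).

What the generator does **not** emulate: the real cohort's skewed and
heavy-tailed marginals (CRP is plainly log-normal-like), feature-specific
missingness patterns (missingness is injected independently per cell),
any time structure in the environmental variables, and the unknown true
cross-feature dependence beyond the block-equicorrelation summary.
Passing tests therefore demonstrate that the pipeline recovers structure
*of the kind the cohort reports* under a faithful moment/correlation
emulation — not that it reproduces the restricted data's accuracies,
which are out of reach without the data itself.

## Numerical choices and degenerate inputs

* Zero-variance columns: Fisher score 0; standardization maps them to
  zeros; outlier substitution skips them; Relief-F differences are 0.
* Perfectly separated constant classes (zero within-class variance,
  positive between) are an error for the Fisher score rather than `Inf`.
* Distance correlation is computed through the row-sum identity
  `dCov² = S1 − 2 S2 + S3`; tiny negative `dCov²` from floating-point
  cancellation is clamped to 0, and a constant margin returns 0 by
  convention.
* Ward clustering delegates to `stats::hclust(method = "ward.D2")` on
  Euclidean distances; merge heights are on the distance scale and
  non-decreasing. Tests verify the merge sequence against a naive
  agglomeration that recomputes every Ward cost from scratch.
* The k-NN classifier is implemented in-package because the benchmark
  grid requires Manhattan distance and inverse-distance vote weights, and
  the wrapper-search equivalence checks require fully deterministic
  tie-breaks (neighbor ties by training index, vote ties toward class 0).
* Chi-square uses no continuity correction; with the printed season
  contingency table this reproduces the published 36.091 exactly.
* The metric pair reported for hard 0/1 predictions satisfies
  `rmse² = 1 − accuracy` identically; `R` is the Pearson correlation
  between true and predicted labels and `std` the sample SD of signed
  residuals (≈ RMSE when errors are balanced) — both stated here because
  the benchmark tables this suite mirrors leave them undefined.

## Problem sizes used by the test and acceptance suites

Oracle-equivalence suites run on 100 random instances (Ward, n ≤ 8 items;
distance correlation, n ≤ 50) and 15–20 wrapper-search instances with ≤ 6
features under 1-NN. Calibration checks use 2000 null t-test replicates
(n = 20 per group), 20 null-AUC seeds at n = 2000, and 10 MI seeds at
n = 2000. Recovery checks use 20 cohorts of 339 per group with 6
informative features at Cohen's d = 0.6 against 14 noise features (a
moderate clinical effect size, fixed before measurement), and 50 cohorts
for the platelet-isolation rate. These sizes keep the default suite deep
enough to exercise every contract while remaining quick on a laptop.

## Known limitations

* Gaussian marginals understate tail behavior of inflammatory markers;
  moment recovery is asserted only where floor truncation is negligible.
* The greedy wrapper passes are single-pass by design (no floating
  search); a feature rejected early in the forward pass is never
  reconsidered.
* The plug-in MI estimator is positively biased at small n (≈ (B−1)/2n
  nats); the bins default keeps that bias ~0.002 nats at n = 2000 but it
  grows quickly below a few hundred samples.
* `R` (label correlation) is `NA` when a classifier predicts a single
  class, rather than an arbitrary 0.
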