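---
title: "Choosing and timing behavioral test batteries: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Choosing and timing behavioral test batteries: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(batterysel)
library(dplyr)
```

## The problem

Pre-clinical studies of repetitive mild traumatic brain injury (rmTBI) in
mice have no standard battery of behavioral outcome tests. Different labs
measure different subsets of the Morris water maze (MWM), elevated plus maze
(EPM), open field (OF), forced swim (FST), rotarod and other endpoints, at
different weeks after injury. When many such experiments are pooled
retrospectively, the data form a sparse mice-by-outcomes matrix: no mouse was
tested on everything, no test was run on every mouse, and missingness is
structural (whole experiments lack whole tests), not random.

`batterysel` asks two questions of such a pooled cohort:

1. **Which combination of outcome parameters, measured at which week,
   best discriminates injured (TBI) from uninjured (sham) mice?**
2. **Does pooling heterogeneous experiments predict a behavioral outcome
   better than single homogeneous experiments?**

## The outcome taxonomy

Every measured parameter is identified by a code `TEST[:SUBTYPE][INDEX]:W<week>`
(e.g. `MWM:H5:W13` — MWM hidden trial 5 at week 13; `OF:S:C:W4` — open field,
square arena, center zone, week 4). Codes live in a three-level taxonomy:

* **level 1** — behavioral category: cognitive, anxiety/depression, motor
  (plus a severity branch holding per-procedure loss-of-consciousness times,
  which serve as covariates, not candidate outcomes);
* **level 2** — the test (MWM, EPM, OF, ...);
* **level 3** — the parameter family within a test (MWM hidden trials, OF
  circle position, ...), whose members are individual trials or days.

The registry also records, per family, whether *higher* raw values indicate
good outcome (directionality) and whether a parameter is *redundant* — a
session complement carrying no degree of freedom (EPM closed-arm time, OF
wall-zone times). Redundant parameters stay in the data model but are
excluded from combination searches by default: they can only duplicate their
siblings' information while doubling the search space. Severity (LOC)
parameters are likewise excluded from candidate sets by default; they are
exposure covariates, and the selection cascade is about behavioral tests.

```{r registry}
reg <- default_registry()
reg %>% count(level1, level2) %>% head(8)
```

## Sparse cohorts and the complete-case core

Missingness is encoded by the absence of a measurement row — no sentinels.
`availability_profile()` ranks outcomes by the fraction of mice measured and
computes, at each rank, the *cumulative fraction*: the fraction of mice
measured on that outcome **and** every higher-availability outcome. The last
rank with a positive cumulative fraction defines the maximal complete-case
core, the largest set of outcomes on which a nonempty complete-case matrix
exists. PCA and the clustering scan require complete cases, so they operate
on this core.

## Classification: bootstrapped AUC of guarded logistic models

Discrimination is measured by logistic regression scored with the area under
the ROC curve, computed by pair counting (the Mann–Whitney statistic with
ties counted 1/2). Design choices:

* **Adjustment.** Every model includes the number of TBI/sham procedures as
  a numeric covariate. In cohorts like the one the generator emulates,
  between-experiment differences among untreated sham mice track the number
  of anesthetic events, so anesthesia dose is a confounder of any pooled
  comparison. A factor encoding would multiply parameters past the sample
  guard; the count is used as-is.
* **Sample-size guard.** A model runs only if there are at least 10
  complete-case mice per predictor, counting behavioral predictors plus the
  adjustment covariate but not the intercept. This is applied before any
  fitting, and refusals are logged, not silently skipped.
* **Bootstrap.** 25 iterations; each resamples mice with replacement, fits
  on the resample and computes the AUC **on the out-of-bag mice**. In-sample
  AUC would be optimistically biased, most severely for the small complete-case
  subsets where the guard binds hardest; out-of-bag evaluation is the
  standard resampling-validation convention. Iterations whose resample or
  out-of-bag set is single-class are redrawn (at most 10 times, then
  skipped). The mean and SD over iterations summarize the model. A 10-fold
  stratified cross-validation variant (`cv_auc()`) is provided for
  comparison.
* **Orientation.** AUC below 0.5 is reported as-is; the fitted model fixes
  the score orientation, and flipping would hide miscalibrated models.
* **Degenerate fits.** IRLS runs to a 1e-8 deviance tolerance with a hard
  cap of 50 iterations. Under complete separation the cap stops iteration;
  the score *ranking* — all the AUC uses — is unaffected.

Per-family discrimination over time is summarized by an ordinary
least-squares parabola through the per-week AUC means
(`fit_time_trend()`). The optimal week is the parabola's vertex when it
opens downward inside the observed range, otherwise the boundary week with
the highest fitted value (earliest on ties). Weeks outside the observed
range are never reported: the data cannot support extrapolated optima.

## The selection cascade

`run_cascade()` implements a three-stage search mirroring the taxonomy:

1. **Level 3.** Within each (parameter family, week) group, every nonempty
   subset of members passing the guard is scored by bootstrapped AUC; the
   best subset *qualifies* when `AUC mean − AUC SD > 0.75` (strict). The
   subtraction of one SD penalizes unstable small-sample winners.
2. **Level 2.** Per test, the variables of the test's qualified level-3
   models are pooled. Because of structural missingness, all of them rarely
   share complete cases; `maximum_model()` finds the **largest** subset
   whose jointly complete cases still satisfy the guard (exhaustive
   branch-and-bound, exploiting the monotonicity that adding a variable
   never increases the complete-case count). The best subset within the
   maximum model is then found as at level 3.
3. **Level 1.** The same, per behavioral category, pooling qualified
   level-2 winners.

All tie-breaks are deterministic (higher AUC mean, then fewer variables,
then more mice, then canonical code order), and each (level, group) derives
its own seed stream from the global seed, so adding a group never shifts
another group's draws. Both choices exist to make reports reproducible and
diffable. The per-group bootstrap draws are independent across levels; the
qualification rule is applied at every level. Subset searches are exhaustive
with a configurable size cap (default 20 variables) guarding pathological
inputs.

## Clustering: the k-means / ARI combination scan

`combination_scan()` asks whether combinations of outcomes *unsupervisedly*
structure mice into injured and uninjured groups: for every combination of
the core outcomes (32,767 subsets for a 15-outcome core), the complete
cases are rescaled, partitioned by Hartigan–Wong k-means (Euclidean metric,
best of 10 restarts), and scored against the true TBI/sham labels with the
Hubert–Arabie adjusted Rand index. k defaults to 2 because the target
structure is the injured/uninjured split; cluster-to-class matching is
unnecessary since the ARI is permutation-invariant. Restart count and k are
configuration; the per-subset seed is derived from the subset's codes. For
interactive use, `max_per_size` subsamples combinations per size while the
full binomial counts stay reported.

## Heterogeneity: study accumulation

`accumulate_studies()` fits ordinary least-squares models predicting one
behavioral outcome (default `MWM:H4:W2`) from loss of consciousness after
the *first* procedure, the number of procedures, and treatment (one-hot,
"none" as reference). For each number of studies m, up to 25 distinct random
subsets of the eligible experiments are pooled (complete cases; outcome
outliers beyond 5 SD dropped), and each subset is scored by 10 bootstrap
iterations of out-of-bag standardized RMSE — the RMSE divided by the pooled
subset's outcome SD. Using the pooled-subset SD (not a per-bootstrap or
global SD) keeps the denominator stable within a subset while letting the
curve be compared across m; the convention is documented because reasonable
alternatives exist. A value of 1 means the model predicts no better than the
pooled mean.

## The synthetic cohort generator

No public raw data exist for cohorts like this, so the package ships a
generator whose defaults encode the study conditions the analyses assume.
Measurement values follow

```
value = baseline
      + dir * effect * SD * 1[TBI] * (1 − attenuation * 1[treated])
      + anesthesia_slope * n_hits
      + experiment_effect
      + Gaussian noise,
```

where `dir` points toward the family's *bad* direction, the experiment
effect is a per-(experiment, family) Gaussian draw, and values are truncated
at zero (latencies, durations and counts have floors; baselines sit several
SDs above zero so truncation is rare). Loss-of-consciousness times rise
monotonically with drop height over an anesthesia-only baseline, so sham
mice still receive near-baseline draws. Redundant parameters are generated
as session complements of their siblings (e.g. closed-arm time = 300 s −
open-arm time), so they genuinely carry no degree of freedom. Identical
(design, effects, seed) triples produce byte-identical output.

Two designs are built in:

* `fixture_design()` — 1203 mice in 58 experiments reproducing,
  exactly, the published design margins: 675 TBI / 528 sham; the drop-height,
  schedule, age and treatment margins; every per-(parameter, week)
  measurement count; and a 301-mouse complete-case core (180 TBI / 121 sham)
  on the 15 highest-availability outcomes. Only the margins are published;
  the joint allocation is one deterministic choice (core mice receive
  exactly the core battery plus LOC, remaining counts ring-allocated over
  the other mice, session-linked parameters sharing allocations), validated
  cell-by-cell at build time. The default `fixture_effects()` plant a
  concave-in-week effect profile peaking at week 13 with MWM families
  strongest (1.5 SD) and motor weakest (0.15 SD) — chosen once so that the
  qualitative ranking the method should recover (MWM best, ~3–4 months
  optimal, motor unqualified) is present, and never tuned afterwards.
* `planted_week_effect_design()` — a fully crossed recovery design: one MWM
  family carries a concave week profile with known peak; anxiety and motor
  families carry nothing. Used to check that the cascade finds the peak-week
  variable and the time-trend fit locates the peak.

What the generator does **not** emulate: mechanistic behavior (swim paths,
learning curves within a session), non-Gaussian measurement distributions,
floor/ceiling pile-ups beyond simple truncation, drift over calendar time,
and any correlation between a mouse's outcomes beyond what shared group,
treatment, dose and experiment effects induce. Passing tests therefore show
that the estimators recover planted structure under clean Gaussian
conditions — not that real behavioral data satisfy those conditions.

## Numerical conventions and edge cases

* Outlier screen: z-scores computed once on the input; a mouse exceeding
  |z| > 5 on any column is dropped whole (keeping the complete-case
  structure intact rather than punching new holes), and the survivors are
  re-standardized. The screen is single-pass by definition and hence
  idempotent.
* PCA is computed by SVD of the unit-variance matrix; under that scaling it
  coincides with correlation-matrix PCA. Loading signs are fixed by making
  each vector's largest-magnitude entry positive.
* Group ellipses in PC space are 1-SD dispersion ellipses of the
  within-group score covariance (a "68%" ellipse), not standard-error
  ellipses.
* Availability ties are broken by canonical code string; all orderings in
  reports are deterministic.
* The standardized-RMSE SD uses the n−1 convention; predicting the mean of
  n observations therefore gives √((n−1)/n), not exactly 1.

## Problem sizes used in the tests

The shipped tests exercise the estimators at sizes a reviewer can re-run at
a desk: recovery designs of 240–400 mice, bootstrap B = 25, 20-seed
Monte-Carlo loops for the cascade recovery rate, full combination scans at
up to 6 outcomes with subsampled scans above that, and accumulation runs of
12–20 studies of 30–40 mice. These sizes were chosen as the smallest at
which the planted effects are comfortably detectable; the pipeline itself
has no such limits.

## Known limitations

* The cascade's qualification threshold (0.75) and guard (10 mice per
  variable) are conventions, not estimates; both are configuration.
* Bootstrapped out-of-bag AUC is slightly pessimistic relative to in-sample
  evaluation; absolute AUC levels shift by a few points depending on this
  convention, which is why the package reports the convention explicitly.
* With heavy structural missingness the maximum model is a greedy-looking
  but exact combinatorial object; it can still exclude an individually
  excellent variable measured on the "wrong" mice (the FST-style case:
  strong alone, incompatible with everything else). The refusal log and the
  level-3 table make such exclusions visible.
* `mouse_id` is the unit of independence; repeated measures within a mouse
  across weeks are treated as separate variables, not longitudinal data.
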