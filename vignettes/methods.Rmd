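---
title: "Methods: discrete-time AKI risk modelling and adjMMD transportability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discrete-time AKI risk modelling and adjMMD transportability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(akitransport)
```

## The problem

Hospital-acquired acute kidney injury (AKI) is common, morbid, and — because
serum creatinine (SCr) is measured routinely — predictable hours to days in
advance from ordinary EHR data. A model trained at one hospital, however,
rarely performs as well at another: patient mix shifts, laboratory panels
differ, and coded vocabularies (RxNorm, ICD, CPT) are mapped with different
granularity, so whole features can be absent at a new site. This package
implements the two halves of that story as one toolkit:

1. a **discrete-time survival gradient-boosted tree** (DS-GBT) that predicts
   the onset of KDIGO-staged AKI within a 24- or 48-hour window, and
2. the **adjusted maximum mean discrepancy (adjMMD)**, a gain-weighted,
   missingness-penalised kernel two-sample statistic between the training
   data and a candidate deployment site that predicts how much AUROC the
   transported model will lose there — before any outcome is collected at
   the target.

## KDIGO labels as a discrete-time process

AKI is staged from SCr alone (urine output is unreliable outside critical
care and is excluded by construction):

* stage 1 ("any AKI"): SCr rise of at least 0.3 mg/dL within 48 h, or
  SCr at least 1.5x baseline;
* stage 2: SCr between 2.0x and 2.9x baseline;
* stage 3: SCr above 3x baseline, or SCr reaching 4 mg/dL through an acute
  rise of at least 0.3 mg/dL, or initiation of renal replacement therapy.

The *baseline* is the most recent SCr within a 7-day lookback (pre-admission
records included); when none exists the admission SCr substitutes. The stage
is evaluated at every measurement and carried forward until the next one,
yielding a per-day stage sequence truncated at `tau = 7` days
(independent right-censoring; stays longer than a week are censored, not
modelled). Day 1 is the admission calendar day and all windows are closed on
both ends in days.

Two readings of the 48-hour criterion are possible; the package defaults to
the more conservative one — the rise relative to the *minimum* SCr in the
preceding 48 h — with `delta48_ref = "recent"` available for the
latest-prior-value reading.

The discrete-time design rows are person-periods: for the task
"first stage >= s\* onset within `(t, t + dt]`" an encounter with onset at
day `o` contributes rows `t = 1..o-1` (the last `dt` labelled 1); an
event-free encounter contributes `t = 1..censor - dt`, all 0. Windows that
would extend past discharge or `tau` without an event are dropped as
right-censored rather than labelled. A brute-force window enumerator in the
test suite confirms this construction exactly.

## Automated feature curation

Six steps, applied per site: (1) numeric observations beyond the population
1st/99th percentile are removed (streams with fewer than 100 values are left
untouched); (2) diagnosis/procedure codes are one-hot binary, sticky from
first coding; (3) medications enter as *cumulative exposure days*, not
presence; (4) repeated within-day numerics resolve to the most recent value;
(5) gaps are filled by sample-and-hold from earlier days only — a feature at
day *t* never uses later information, and a test rebuilds the matrix from
truncated tables to prove it; (6) derived features: per-lab change since the
last observation, daily min/max of systolic and diastolic pressure, and the
within-day least-squares hourly BP slope.

Lookback defaults are 7 days for labs and 90 days for diagnoses/procedures
around the stay; the one-hot vocabulary is fixed on the derivation split, so
codes unseen in training score as zero and features absent at a target site
surface as 100% missing — which is exactly what the adjMMD missingness
penalty consumes.

## The risk model

XGBoost with `binary:logistic` loss on the person-period rows. Splits are by
encounter, never by row: encounters admitted after the temporal cutoff form
a temporal validation set, the remainder randomise 70/15/15 into
derivation/calibration/internal. Hyperparameters (depth 2-10, learning rate
0.01-0.1, minimum child weight 1-10, row/column subsampling) are selected by
encounter-grouped cross-validated AUROC under a sequential random search —
the search contract is "any sequential optimiser at equal budget" — with the
tree count set by early stopping (100 rounds patience; final refit holds out
10% of derivation encounters). Five folds are the default; ten are a common
alternative and configurable. Missing numerics are handled by the learned
default-direction splits; no class reweighting is applied.

Calibration uses logistic recalibration on the logit of the raw score
(isotonic optional) fitted on the calibration partition; the map is forced
monotone.

## Evaluation

AUROC is the rank statistic (ties one half, verified against exhaustive pair
counting); AUPRC is step-interpolated. Confidence intervals bootstrap the
*encounter* (rows within a stay are dependent), B = 200 by default.
Calibration is the Hosmer-Lemeshow score over risk deciles with the
`(1 - p)` denominator variant (plain Pearson by flag) and `df = g - 2`;
two HL scores are compared by `F = (HLS_a/df_a)/(HLS_b/df_b)`. Note the
`g - 2` reference applies to scores fitted on the evaluated data; externally
fixed scores concentrate near `g`, which the unit suite documents. DeltaAUC
is the source temporal AUROC minus the target-site AUROC; positive values
mean deterioration.

## Interpretation

TreeSHAP attributions on the log-odds scale decompose every prediction
exactly (the local-accuracy identity is asserted to 1e-6). Marginal-effect
summaries bin each feature into 50 equal-count bins and report the mean SHAP
with a percentile interval over 100 row-bootstrap replicates. `exp(phi)`
converts a log-odds attribution to a fold-change in odds, reported to one
decimal below 10 and to the nearest integer above. Cross-site agreement uses
the soft rank `f(r) = exp(-r/s)` with `s = 100` and, per feature, the
fraction of sites ranking it in the top 100 plus the median/IQR of soft
ranks; a feature unranked at a site contributes soft rank 0 there (an
explicit choice — the alternative, dropping such sites, overstates
agreement).

## adjMMD

For each feature `k` the unbiased MMD U-statistic between source sample
`x` and target sample `y` is

```
MMD_k = mean_{i != j} K(x_i, x_j) + mean_{i != j} K(y_i, y_j)
        - 2 mean_{i, j} K(x_i, y_j),    K(a,b) = exp(-(a-b)^2 / (2 h^2))
```

computed after standardising both samples by the source mean/SD, with `h`
from the median heuristic on the pooled observed sample (per feature;
subsampled to 2,000 values for the quadratic kernel sums). Negative values
are kept — clipping would bias the aggregate — with a clip flag available.

Plain MMD is undefined for an absent feature and too gentle on partial
missingness, so missing target values are imputed *adversarially*: draws
from the bottom and top 1% of a kernel density estimate of the source
distribution (`kde_tails`, the default), making missingness strictly more
expensive than any real distribution discrepancy. The standard-error band
variant (draws outside `mean +/- z_0.99 * s / sqrt(n)`) is implemented
verbatim as an option but its band shrinks with `n`, so it penalises weakly
for large samples — documented, not default. Binary one-hot features use
the same kernel on raw 0/1 samples; an absent code is imputed from the
complement Bernoulli distribution of the source.

The aggregate over the model's top-K gain-ranked features is the
weight-renormalised *mean* `adjMMD(K) = sum_{k<=K} w_k MMD_k / sum w_k`.
A weighted sum of nonnegative terms could never decrease as well-matched
features are added, but the observed behaviour of the metric is exactly that
recovery — hence the mean.

`minimal_feature_set()` correlates per-site `adjMMD(K)` with per-site
deltaAUC for every K and returns the smallest K attaining the maximum of the
Pearson curve; the transportability line `deltaAUC = b0 + b1 * adjMMD` is
ordinary least squares at that K. `predict_target_auc()` offers the
intercept-free `slope_only` arithmetic alongside the `full` line, and its
*reported* value rounds down to two decimals: a deliberately conservative
report that never overstates transported performance (the raw expectation is
returned too).

The mixed-effect generalisation pools (deltaAUC, adjMMD) pairs over models
`i` and derivation sites `j` with a fixed slope, a random intercept by site
and random slopes by model and site, fitted by REML via lme4. The
sample-/model-agnostic tests fit the line within one group, score every
group's mean squared prediction error under it, and compare same-group with
different-group errors by a two-sided Welch test (rank-based alternative
available).

## The synthetic multi-site generator

No clinical data ships with the package; every claim is exercised on a
simulator that reproduces the *statistical structure* the pipeline assumes:
patient-level latent means for labs and vitals with daily noise, Bernoulli
medication exposure with persistence, sticky diagnoses, and a per-day
logistic hazard for AKI onset driven by named covariates (cumulative
vancomycin days, BP slope, bicarbonate, hemoglobin, white count, albumin,
age, BMI, sepsis). On event, the SCr trajectory jumps to the *mid-interval*
of the intended KDIGO stage (ratios 1.7 / 2.4 / 3.4) so round-trip staging
is not boundary-flaky. All randomness flows from one seed through named
substreams, so each table is independently reproducible.

Design choices that matter and why:

* **Event rates.** Real-world moderate-to-severe AKI prevalence is about
  2% of encounters, observed at registry scale (hundreds of thousands of
  stays). The benchmark simulates a few thousand encounters per site, where
  a 2% rate leaves ~20 derivation events — pure noise. The defaults emulate
  a higher-acuity service (any-AKI ~16-19%, stage >= 2 ~6-8%) so that the
  pipeline's statistical behaviour, not event-count starvation, is what the
  tests measure. This is a scaled-down-study choice, stated once here.
* **Paired sites.** All target sites in
  `make_transportability_benchmark()` share one random substream and differ
  only in the shift applied (a common-random-numbers design). Site-level
  cohort sampling noise would otherwise dominate a 6-point correlation; the
  pairing also makes the missingness masks nested along the ladder.
* **Convex shift ladder.** Discrimination loss is steepest at low
  missingness and saturates, so shift intensity grows as the square of the
  grade, spreading sites across the responsive range.
* **All-or-nothing vocabulary.** The medication code is either mapped at a
  site or absent from its dictionary; partial medication capture would
  encode false zeros, which damage ranking non-monotonically and correspond
  to no real mapping failure mode.

What the generator does *not* emulate: code hierarchies and granularity
mismatch within vocabularies, informative observation timing, care-bundle
feedback on treatment, inter-feature correlation beyond the shared hazard,
and length-of-stay dependence on severity. Passing tests therefore show the
machinery is correct under the stated structure — not that any particular
clinical performance level will be reached on real data.

## Numerical choices and degenerate inputs

* Median-heuristic bandwidth per feature; degenerate (constant) pooled
  samples fall back to `h = 1` (binary features floor at 0.5).
* Zero-variance source features in the adversarial imputer fall back to an
  offset constant, with a message.
* Constant predicted risks collapse the HL statistic to a single bin and a
  score of 0; empty risk deciles merge with neighbours.
* Gain ties break lexicographically by feature name, making rankings
  deterministic; split remainders go to the derivation partition.
* Mixed-model fits ignore singular-fit warnings (variance components may
  truly be ~0) but report convergence messages rather than silently falling
  back.

## Problem sizes

The test suite trains its fixture models on 900-encounter cohorts and runs
the full benchmark at 6 sites x 2,000 encounters with a 6-draw
hyperparameter search; the acceptance script uses the same sizes. These are
the package's reference conditions: large enough that AUROC differences of
~0.03 are resolvable, small enough to run on one CPU in minutes.

## Known limitations

* The per-feature MMD ignores joint structure; a site could match every
  marginal and still differ in correlations (the construction is
  deliberately per-feature).
* The transportability line is fitted on a handful of sites; its intervals
  are accordingly wide, and the mixed-effect model is the honest summary
  when several models/derivation sites are available.
* eGFR-based eligibility uses the CKD-EPI 2009 creatinine equation
  (configurable), applied to the earliest SCr as the admission estimate.
* Urine-output staging, eGFR-based CKD staging and ICD-based AKI phenotypes
  are out of scope by design.
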