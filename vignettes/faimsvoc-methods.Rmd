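---
title: "Classifying FAIMS VOC profiles: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying FAIMS VOC profiles: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faimsvoc)
```

## The measurement and the data model

Field asymmetric ion mobility spectrometry (FAIMS) separates the ionised
volatile organic compounds (VOCs) in a sample's headspace by how differently
they drift under alternating high and low electric fields. The instrument
scans two axes — the dispersion-field strength (0–100% of maximum, 51 steps)
and a compensation voltage (+6 V down to −6 V, 512 steps) — and records the
ion current at each grid point, once per ion polarity. One sample therefore
yields two 51 × 512 *dispersion plots*, i.e. 2 × 51 × 512 = 52,224 data
points. Samples are measured in triplicate and the second replicate is
carried into analysis (an empirical convention from earlier headspace work:
the first run still equilibrates, the third can be depleted; the choice is a
configuration key, not a constant).

Faecal VOC profiles reflect gut microbial metabolism, which is profoundly
altered in severe acute malnutrition (SAM). The pipeline's purpose is to ask
whether those profiles separate clinically defined groups — above all,
children with complicated SAM who died within six days of admission from
those discharged alive — and to report that separation the way clinical
classification studies do: pooled cross-validated ROC/AUC with confidence
intervals and permutation p-values, an operating point, and predictive
values at cohort prevalence.

## Pipeline

1. **Combine polarities.** Each subject's two matrices are flattened into a
   single 52,224-vector (positive block first, row-major with compensation
   voltage innermost). The index map is a documented bijection, so any
   selected feature back-maps to (polarity, dispersion field %, CV volts)
   for feature-location maps.
2. **Background threshold.** Most pixels are background ridge or empty
   space. A pixel is retained when its across-sample standard deviation
   exceeds the 50th percentile of that statistic (both configurable, or a
   mean-absolute-intensity statistic instead). A pixel that never varies
   cannot discriminate, so the rule discards only provably uninformative
   pixels while halving compute. Crucially the rule is *label-blind*: it can
   be fitted once on all samples without leaking class information into
   cross-validation. A per-fold refit is available for strictness.
3. **Cross-validation with in-fold selection.** Stratified tenfold CV. Within
   each fold, every retained pixel is scored on the 90% training split by a
   two-sample Wilcoxon rank-sum test and the k smallest two-sided p-values
   are kept (k = 100 by default; 50 and 20 are also standard). A classifier
   is trained on those features and scores the held-out 10%. After ten folds
   every sample has exactly one out-of-fold score, and those pooled scores
   feed a single ROC per comparison.
4. **Classifiers.** Four families, as pluggable backends: random forest
   (1000 trees), Gaussian process (radial kernel, automatic bandwidth),
   support vector machine (radial kernel, Platt-scaled probabilities) and
   sparse logistic regression (L1 penalty chosen by inner 5-fold CV). All
   emit probability-like scores for a stated positive class; all stochastic
   steps are seeded per fold. Hyperparameters are declarative overrides —
   documented defaults rather than silent backend defaults.
5. **Reporting.** AUC (Mann–Whitney concordance; the trapezoidal curve
   integral equals it exactly), 95% CI by stratified bootstrap (2000
   resamples; DeLong as an option), a one-sided permutation p-value against
   AUC = 0.5 (10,000 label permutations), the Youden-optimal operating
   point, and PPV/NPV at the comparison's prevalence.

## Why in-fold selection is the load-bearing choice

With 52,224 candidate features and ~57 samples, selecting features on the
full dataset *before* splitting lets the test folds influence which features
the classifier sees, and pure noise then cross-validates far above chance.
The package treats this as a first-class, testable property rather than
folklore: `run_cv(selection = "pooled")` implements the leaky variant
deliberately, and the test suite verifies on null synthetic cohorts (no
class effect whatsoever) that the median pooled AUC of the honest pipeline
stays near 0.5 while the leaky variant exceeds 0.65 — in practice it
approaches 1, which is exactly why the distinction matters at this
dimensionality.

## The comparisons

Eleven built-in two-arm contrasts mirror the study design: SAM vs healthy
controls (an instrument-validation contrast); death within 6 days vs
discharge; early death (day 1–3) vs discharge; late death (day 4–6) vs
discharge; early vs late death; and six morbidity contrasts over known
mortality risk factors (WAZ ≤ −3, oedema, diarrhoea, pneumonia, HIV
serostatus with unknowns excluded, and age dichotomised at 2 years). All but
the control contrast are restricted to the SAM cohort; subjects matching
neither arm (e.g. missing the defining variable) are excluded and counted.
The positive class of every report is the first arm, and each report row
states the orientation — published tables often leave it implicit, which is
why `reconstruct_confusion()` searches both orientations when checking
printed sensitivity/specificity pairs for integer consistency.

Baseline characteristics use a pooled-variance (Student) two-sample t-test
for continuous variables — computed either from raw values or directly from
printed mean/SD/n summaries via `t_test_summary()` — a two-proportion z-test
without continuity correction for binary variables, and chi-squared for
multi-level categoricals. Pooled rather than Welch is deliberate: it is the
test that reproduces the source table's printed p-values from its own
printed summaries (Welch gives 0.03/0.02 where the table prints 0.04/0.03).

## Statistical choices and numerical details

* **Rank-sum p-values.** Exact (closed-form Mann–Whitney null distribution)
  when both classes have ≤ 10 samples and the feature is tie-free; exhaustive
  enumeration of label assignments for small tied cases (up to
  `choose(n, nA)` ≤ 20,000); otherwise the tie-corrected,
  continuity-corrected normal approximation, matching `stats::wilcox.test`.
  A feature constant across all samples gets p = 1 by convention and ranks
  last. Ties in p rank by ascending flat index — reproducibility over
  arbitrariness.
* **Ranking key.** Features are ranked by two-sided p-value, not by |U|;
  for equal arm sizes the orderings coincide, and the p-value remains
  well-defined when fold arms are unequal.
* **Folds.** Stratified by class: each class is shuffled and dealt
  cyclically, so fold sizes differ by ≤ 1 and each fold's class count is
  within one of the global ratio. With only 19 events, unstratified folds
  can be event-free and distort the pooled ROC. A class smaller than the
  fold count falls back to unstratified folds with a warning.
* **Degenerate cases.** A classifier failure in a fold skips the fold and
  flags the result incomplete rather than aborting the run; an all-tied
  score vector gives AUC 0.5 with a CI containing 0.5; an operating point
  with no positive (or no negative) calls yields a flagged undefined
  PPV (NPV).
* **Rounding.** Reports display half-up to 2 decimals (the convention of
  clinical tables — base R's round-half-even would print 0.575 as 0.57);
  JSON/CSV outputs keep full precision.
* **Determinism.** Every stochastic step (folds, classifier fits, bootstrap,
  permutation, simulation) derives its seed from the run seed; a rerun under
  an archived configuration is bit-identical.

## The synthetic cohort generator

Because the raw clinical dataset cannot ship with the package, the generator
produces cohorts on which every pipeline stage is exercisable and *checkable
against known ground truth*:

* **Matrices.** A smooth background ridge whose CV position drifts with
  dispersion field (as the real reactant-ion peak does) and strengthens with
  field; sparse 2D Gaussian analyte peaks; iid per-pixel Gaussian noise
  (SD 1 in arbitrary ion-current units); and a per-run log-normal gain
  jitter (SD 0.05) modelling the run-to-run variability that motivates
  replicate measurement. Three replicates per sample by default.
* **Class effects.** Selected peaks gain amplitude `d × noise SD` (and/or a
  CV shift) for subjects in a designated metadata arm — by default a d = 2
  effect on three peaks for the died arm. The class-informative peaks sit
  away from the background ridge, as genuinely discriminatory analyte peaks
  do; pixels on the ridge are dominated by gain jitter, which is exactly
  what the background threshold removes.
* **Ground truth.** Emitted with the data: the planted pixel set is defined
  once as the pixels whose expected between-arm difference is at least half
  the maximum planted effect. Default peak widths (5% of field, 0.55 V) were
  sized analytically so this set is roughly 200 pixels at the reduced
  51 × 128 test geometry. Recovery metrics (`recovery_fraction()`) are
  first-class outputs.
* **Metadata.** Arm sizes 38 discharged / 9 early deaths / 10 late deaths /
  7 healthy controls, with per-arm clinical marginals (age, MUAC,
  anthropometric z-scores, morbidity rates, HIV distribution including the
  "unknown" category, site mix) matching the study's baseline table, plus
  consistency rules: a day of death (1–6) exists iff the subject died;
  controls never die and carry no SAM morbidity flags. Ages are truncated
  to the eligibility window (6–60 months; 6–72 for controls), so realised
  means sit slightly above the nominal ones.

**What passing on synthetic data does and does not show.** The generator
emulates the geometry, background structure, noise scales and cohort
composition — enough to verify leakage control, ranking power, recovery and
calibration. It does not emulate ion chemistry, peak shape families,
inter-site batch effects, or correlated biological variation between
subjects; a pipeline that passes here is statistically sound, not clinically
validated.

## Problem sizes used by the tests and the acceptance script

Simulation-heavy checks run at the full cohort size (57 SAM + 7 controls)
but reduced matrix geometry, 51 × 128 (13,056 features per sample), with one
replicate per sample — the replicate dimension is irrelevant to null or
recovery behaviour, and the narrower CV axis preserves the
features-to-samples ratio regime (~230:1) that makes selection leakage
dangerous. The leakage guard uses 50 null cohorts; signal recovery uses 20
cohorts with the default d = 2 effect; calibration checks use 300 null
permutation replicates and 200 bootstrap replicates at n = 30 per class.
Unit-level oracles (exact rank-sum enumeration, brute-force AUC pair
counting, exhaustive Youden scans) run at small n where exhaustive
computation is feasible.

## Reproducing the published numbers

Three kinds of published quantities have three different statuses:

1. **Arithmetic consequences of printed numbers** — PPV/NPV implied by a
   row's printed sensitivity/specificity and arm sizes, and the baseline
   table's t-test p-values from its printed summaries — are reproduced
   exactly by `reconstruct_confusion()` + `predictive_values()` and
   `t_test_summary()`.
2. **Properties of the method** — leakage control, recovery, calibration —
   are reproduced on synthetic cohorts with ground truth.
3. **The cross-validated AUCs themselves** depend on the raw instrument
   exports (supplementary material) and on unstated seeds and
   hyperparameters. `reproduce_supplementary()` (and
   `scripts/reproduce_supplementary.R`) reruns the identical pipeline given
   that dataset in the package interchange format; agreement within roughly
   ±0.10 per AUC is the realistic expectation for a stochastic pipeline
   rerun with different seeds.

## Known limitations

* No baseline correction, peak alignment or deconvolution: pixels are
  features. Cross-instrument transfer would need alignment the package does
  not attempt.
* The rank-sum selector scores pixels independently; spatially contiguous
  peaks enter as multiple correlated features rather than one "peak"
  feature.
* Multiple-testing correction is deliberately absent from selection — the
  ranking orders features, it does not test them; no per-feature inference
  is reported.
* The percentile bootstrap slightly undercovers at very small n; the DeLong
  interval is available where an asymptotic interval is preferred.
* Case–control matching of the original design is not modelled; the
  generator reproduces marginals, not the matching structure.
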