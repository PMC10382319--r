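---
title: "Predicting laser-treated retinopathy of prematurity from routine physiological monitoring: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting laser-treated retinopathy of prematurity from routine physiological monitoring: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scientific problem

Severe retinopathy of prematurity (ROP) requiring laser coagulation is
preceded by weeks of abnormal oxygen exposure. Routine neonatal intensive
care monitoring — pulse-oximetry oxygen saturation (SpO2, %), heart rate
(HR, beats/min) and the delivered fraction of inspired oxygen (FiO2,
0.21–1.0) — therefore carries an early predictive signal. `ropvitals`
implements the full analysis chain needed to study that signal on
synthetic cohorts:

1. a generative model of 30-day neonatal SpO2/HR/FiO2 traces with a
   configurable group contrast between laser-treated and untreated
   infants;
2. daily extraction of 13 physiological feature families;
3. a cluster-based permutation test locating postnatal-day windows where
   a family separates the outcome groups;
4. imbalance-aware leave-one-out random-forest classification of ten
   nested model variants; and
5. evaluation with Agresti–Coull intervals, MCC, mid-p McNemar tests and
   threshold sweeps, orchestrated by a reproducible pipeline.

## Synthetic cohort generator

`generator_config()` / `generate_cohort()` simulate a screening
population. Group-conditional demographics mimic an extremely-preterm
case mix: laser-treated infants draw gestational age from N(25.0, 0.9)
weeks and untreated infants from N(26.8, 1.5), truncated to [23, 32);
birth weight is linear in gestational age plus noise, so a minority of
infants violate the <32 weeks / <1500 g inclusion rules and are later
excluded — exclusions are an emergent property, not a hard-coded count.
The outcome prevalence defaults to 0.15 (binomial), or a fixed count via
`n_positive`.

Each signal is a bounded AR(1) baseline with event overlays:

* **SpO2** — setpoint ~ N(93, 1.2) %, within-infant AR(1) with sd 1.5
  and correlation time 600 s, clipped to [0, 100]; overlaid brief
  desaturations (depth 65–78 %, 15–60 s, ≈8/day), deep hypoxic episodes
  (55–70 %, 120–360 s, ≈1.5/day) and hyperoxic plateaus (96.5–99.5 %,
  600–2400 s, ≈3/day).
* **HR** — AR(1) around 160 ± 8 beats/min (sd 7, correlation time
  300 s), positive exponential spikes (rate 24/day, mean amplitude 18 —
  these produce right skew and occasional tachycardia above 200) and
  bradycardic dips (rate 4/day, nadir 70–95, 10–60 s).
* **FiO2** — a step function ≥ 0.21 with baseline 0.21 + Exp(0.04),
  re-drawn at care-event times.

A group contrast is injected on the *latent dials* of the generator, not
on the extracted features: `effect_windows` is a table of
(feature family, day window, effect in SD units) rows, and each family
maps to a dial (e.g. `mean_fio2` shifts the FiO2 setpoint by
0.04 × effect; `n_desaturations` adds 4 × effect desaturations/day;
`hypoxia`/`hyperoxia`/`skew_hr` scale event rates). The defaults place a
+1 SD FiO2 contrast on days 3–30 and ±0.8 SD contrasts on days 5–15,
mirroring the published group differences; `null_effect_windows()`
removes every contrast for calibration studies. Samples are missing
completely at random at rate `missingness_rate` (default 0.02).

What the generator does **not** emulate: monitor artefacts with
structure (probe drop-outs correlated with handling), circadian or
developmental drift over the 30 days, ventilation-mode changes, and any
causal link from FiO2 to SpO2 — signals are conditionally independent
given the group, which is sufficient for studying the statistical
pipeline but not for physiological inference.

## Daily feature families

`build_feature_matrix()` reduces each infant-day to 13 values
(`feature_families()`): mean SpO2, HR, FiO2 and SpO2/FiO2 ratio (mean of
the per-sample ratio); skewness of SpO2 and HR (sample skewness
b1 = m3/m2^1.5 × ((n−1)/n)^1.5, undefined below 3 valid samples);
hypoxic and hyperoxic burden as rectangle-rule area under 80 % and above
95 % (%·min) and as percent of valid time at ≤ 80 % and > 95 % (note the
deliberate boundary asymmetry: hypoxia includes the 80 % bound, hyperoxia
is strictly above 95 %); and counts of desaturation (SpO2 < 80 % for
≥ 10 s), bradycardia (HR < 100) and tachycardia (HR > 200) events.
Event detection merges runs separated by less than `merge_gap` (10 s)
*before* applying the minimum duration, times events by their onset
sample, and lets invalid samples break contiguity. Days without valid
data yield `NA` and are skipped downstream rather than imputed globally.

## Cluster-based permutation testing

For one family, `permutation_test()` arranges the data as a day × infant
matrix and computes a Welch t statistic per day. Days where |t| exceeds
the two-sided Welch critical value at `alpha_cluster` (0.05) are grouped
into contiguous same-sign clusters scored by their mass (sum of t). The
family-wise null is the distribution of the maximum |mass| under
`n_perm` random relabelings of the outcome, and each observed cluster
gets p = (1 + #{null ≥ |mass|}) / (1 + n_perm) — so the smallest
attainable p is 1/(n_perm + 1), and 1999 permutations (the pipeline
default) resolve p = 0.0005. The permutation engine is vectorised: group
sums and sums of squares for all permutations come from two matrix
cross-products, so a 13-family scan of 100 infants at 499 permutations
takes well under a second. `cluster_scan()` runs all families with
sub-seeds derived per family, and `significant_families()` optionally
restricts to clusters overlapping a day window.

## Classification protocol

`model_spec(1:10)` defines the nested variants: all families (1),
cluster-selected families over days 1–30 (2) or days 5–15 (3), the
SpO2/FiO2 ratio alone (4), demographics alone (5), and combinations with
demographics (6, 7) and clinical covariates (8–10). Feature tables have
one `family_d<day>` column per family-day plus cohort covariates.

`loocv_evaluate()` scores every infant with a bagged-tree ensemble
(`randomForest`, 500 trees by default) trained on the others. Inside
each fold — never globally — the majority class is randomly undersampled
to the minority size and missing feature cells are imputed with
training-fold medians. Fold seeds are derived from the master seed and
the held-out infant's id, and rows are first sorted into canonical id
order, so predictions are invariant to cohort arrangement. The predicted
label is positive when the out-of-fold tree vote is ≥ 0.5;
`threshold_sweep()` re-derives labels over a threshold grid to read off,
e.g., the specificity at full sensitivity. `holdout_validate()` trains
once on the training cohort and applies the frozen ensemble to the
independent test cohort; `subgroup_retrain()` reruns LOOCV below a
gestational-age cutoff (default ≤ 28 weeks).

## Evaluation and pipeline

`confusion_metrics()` reports sensitivity, specificity, balanced
accuracy, MCC, PPV and NPV with 95 % Agresti–Coull intervals. The
intervals use the *raw* proportion times the interval denominator as
(possibly non-integer) pseudo-successes — with the total subject count as
the default denominator — because that convention reproduces published
interval sets exactly where a rounded-proportion convention does not.
MCC is defined as 0 when a confusion-matrix margin vanishes.
`mcnemar_midp()` compares paired classifiers with the mid-p binomial
McNemar test (p = 2·P(X ≥ max(b,c)) − P(X = max(b,c)) under
X ~ Bin(b+c, ½), capped at 1). `baseline_table()` contrasts cohort
covariates with χ² (continuity-corrected) or Fisher tests — exact when
any expected cell is below 5 — and Wilcoxon rank-sum tests for continuous
variables.

`run_pipeline()` ties the stages together under one master seed with
per-stage derived sub-seeds: simulate → random 1:1 split **before**
exclusions (so exclusions cannot leak across the split) → inclusion
filters (gestational age < 32 weeks, birth weight < 1500 g, ≥ 80 %
monitor availability over days 1–14, logged with one reason each) →
features → baseline table → cluster scan on the training set only →
LOOCV per model → independent-test validation → threshold sweeps, with
optional tab-separated outputs and a run manifest.

```{r}
library(ropvitals)
cfg <- run_config(
  generator = generator_config(n_infants = 269, seed = 42),
  seed = 42, models = c(4, 5, 7), validate_models = 7)
res <- run_pipeline(cfg, out_dir = "run42")
performance_table(res, digits = 2)
```

## Numerical choices and problem sizes

* Seeds are derived, never global: `derive_seed(seed, tag)` hashes a
  string tag into [0, 2^31), so adding a model never perturbs another
  stage's randomness.
* Rounding for display uses half-away-from-zero and happens only at the
  reporting layer; all stored numbers keep full precision.
* The package's own calibration studies use cohorts of 100–200 infants
  at a 600-s sampling interval with 499 permutations — large enough that
  the family-wise error of the cluster test sits within Monte-Carlo
  error of 0.05 and an injected +2 SD FiO2 contrast on days 5–15 is
  recovered ≥ 95 % of the time, yet small enough to run inside a test
  suite.

## Limitations

* Synthetic traces are stationary within the 30-day window apart from
  the injected contrasts; real neonatal physiology drifts with
  postmenstrual age.
* The cluster test controls family-wise error per family; no correction
  is applied across the 13 families, matching the screening intent.
* LOOCV with per-fold undersampling has high variance in small cohorts;
  balanced accuracy near 0.5 on permuted labels is guaranteed only in
  expectation.
* The generator's group contrast is injected on marginal dials, so
  multivariate models cannot exploit cross-signal interactions beyond
  those the dials induce.
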