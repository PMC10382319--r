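# ropvitals

Early prediction of severe retinopathy of prematurity (ROP) requiring
laser treatment from routine physiological monitoring, on synthetic
neonatal cohorts.

Severe ROP is preceded by weeks of abnormal oxygen exposure that is
visible in bedside monitoring long before ophthalmological screening can
detect disease. `ropvitals` implements the complete statistical pipeline
for studying that signal:

* **Synthetic cohort generator** — 30-day SpO2 / heart-rate / FiO2
  traces per infant (bounded AR(1) baselines with desaturation,
  hypoxia/hyperoxia and bradycardia/tachycardia event overlays),
  group-conditional demographics and clinical covariates, and a
  configurable latent group contrast between laser-treated and untreated
  infants (default prevalence 0.15).
* **Daily feature extraction** — 13 families per infant-day: means of
  SpO2, HR, FiO2 and the SpO2/FiO2 (SF) ratio; skewness of SpO2 and HR;
  hypoxic (SpO2 ≤ 80 %) and hyperoxic (SpO2 > 95 %) burden as area
  (%·min) and percent time; desaturation, bradycardia and tachycardia
  event counts with gap-merging onset detection.
* **Cluster-based permutation testing** (Maris–Oostenveld) — per-day
  Welch *t* statistics, contiguous same-sign suprathreshold clusters
  scored by mass Σt, family-wise p-values from the max-mass permutation
  null: p = (1 + #{null ≥ |mass|}) / (1 + n_perm).
* **Imbalance-aware classification** — ten nested model variants
  (physiology, demographics, clinical covariates and combinations)
  evaluated by leave-one-out cross-validation with per-fold random
  undersampling and training-fold median imputation, plus independent
  test-set validation and gestational-age subgroup retraining.
* **Evaluation** — balanced accuracy, sensitivity, specificity, MCC,
  PPV/NPV with 95 % Agresti–Coull intervals; mid-p McNemar comparison of
  paired classifiers; threshold sweeps; Wilcoxon/χ²/Fisher baseline
  tables.
* **Pipeline orchestration** — random 1:1 train/test split *before*
  exclusion criteria (gestational age < 32 weeks, birth weight
  < 1500 g, ≥ 80 % monitor availability over days 1–14), with every
  stage seeded from one master seed.

## Worked example

Simulate a screening cohort, run the full pipeline, and inspect the
SF-ratio + demographics model (model 7):

```r
library(ropvitals)

cfg <- run_config(
  generator = generator_config(n_infants = 80, sampling_interval = 600,
                               seed = 7),
  seed = 7, models = c(4, 5, 7), validate_models = 7,
  n_perm = 999, ntree = 300)
res <- run_pipeline(cfg)
print(res)
#> Pipeline run (seed 7 )
#>   cohort: 80 infants; 0 excluded; 40 train / 40 test
#>   significant feature families: mean_fio2, mean_sf_ratio, n_tachycardia
#>   model balanced_accuracy sensitivity specificity  mcc  ppv  npv ba_lower
#> 1     4              0.93         1.0        0.86 0.65 0.50 1.00     0.80
#> 2     5              0.73         0.8        0.66 0.31 0.25 0.96     0.57
#> 3     7              0.81         0.8        0.83 0.48 0.40 0.97     0.67
#>   ba_upper sens_lower sens_upper spec_lower spec_upper
#> 1     0.98       0.90        1.0       0.71       0.94
#> 2     0.84       0.65        0.9       0.50       0.79
#> 3     0.91       0.65        0.9       0.68       0.92
```

Training-set LOOCV metrics with Agresti–Coull intervals:

```r
res$evaluations$model7$evaluation
#> Evaluation (TP 4 FP 6 FN 1 TN 29 )
#>   balanced_accuracy  0.81 (0.67-0.91)
#>   sensitivity        0.80 (0.65-0.90)
#>   specificity        0.83 (0.68-0.92)
#>   mcc                0.48
#>   ppv                0.40
#>   npv                0.97
```

Validation of the same model on the independent test half:

```r
res$validation$model7$evaluation
#> Evaluation (TP 5 FP 6 FN 1 TN 28 )
#>   balanced_accuracy  0.83 (0.68-0.92)
#>   sensitivity        0.83 (0.69-0.92)
#>   specificity        0.82 (0.68-0.91)
#>   mcc                0.53
#>   ppv                0.45
#>   npv                0.97
```

Specificity at the largest threshold that still keeps every
laser-treated infant detected (full sensitivity):

```r
sw <- res$sweeps$model7
tail(sw[sw$sensitivity >= 1, ], 1)
#>    threshold sensitivity specificity
#> 50      0.49           1   0.8285714
```

## Package layout

| File | Contents |
|---|---|
| `R/synthetic_cohort.R` | generator config, trace simulation, demographics, missingness, I/O |
| `R/features.R` | daily feature families, event detection, availability, feature matrix |
| `R/cluster_permutation.R` | Welch t, cluster formation, vectorised permutation engine, family scan |
| `R/classification.R` | model specs 1–10, undersampling, LOOCV, holdout validation, subgroup retraining |
| `R/metrics.R` | confusion metrics, Agresti–Coull, mid-p McNemar, ROC, baseline table |
| `R/pipeline.R` | split-then-exclude protocol, orchestration, reporting, manifest |

The methods vignette
(`vignettes/physiology-based-rop-prediction.Rmd`) documents every model
and parameter choice, what the generator does and does not emulate, and
known limitations.
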