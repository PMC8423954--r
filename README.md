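# stabmark

Statistical and machine-learning evaluation of multi-modal biomarker panels
from 2×2 (genotype × treatment) preclinical cohorts, with a calibrated
synthetic-cohort generator for validation against known ground truth.

The package targets the analysis situation of a preclinical
Huntington's-disease trial: four groups of mice — wild-type and R6/2
transgenics, each given vehicle or a candidate therapy ("C31") — measured on
27 continuous biomarkers spanning MRI volumetry (ROI volumes proportional to
total brain volume), diffusion metrics (MD, FA, ODI), R2* relaxometry (raw
and ROI-volume-corrected), plasma cytokines, and creatinine-normalized
urinary p75NTR-ecd.

## What it computes

**Univariate statistics** (`analyze_features()`): per feature and planned
contrast (WT-Veh vs R6/2-Veh, R6/2-Veh vs R6/2-C31, WT-Veh vs WT-C31) —
single-pass 2-SD outlier filtering, a Monte-Carlo-calibrated
Kolmogorov–Smirnov normality screen, dispatch to one-way ANOVA with Fisher's
LSD planned contrasts, Welch's *t*, or Mann–Whitney, two-stage adaptive
Benjamini–Krieger–Yekutieli FDR at 5% within modality families, Cohen's *d*
(pooled SD), noncentral-*t* post-hoc power, and percent change.

**R2\* relaxometry** (`fit_r2star_loglinear()`): mono-exponential decay
fitted by OLS on log signal, `S(TE) = S0·exp(−R2*·TE)`, slope = −R2*
(reported in s⁻¹), plus ROI-volume correction (`volume_corrected_r2star()`).

**Stability selection** (`run_stability()`): the two-step resampling
pipeline — per permutation, a stratified train/test split (6 per class held
out), feature ranking on the training set by linear-SVM weights or
gradient-boosting gain, then classification of nested top-k subsets
(k = 27…2) by distance-weighted 3-NN or a 200-tree random forest
(combos SVM-KNN, SVM-RFC, XGB-KNN, XGB-RFC). Outputs mean ± SD accuracy /
precision / recall per k, and the per-feature percentage of permutations
ranked in the top 15 (the occurrence matrix). `logistic_rank()` gives the
ridge-logistic coefficient ranking of the z-scored panel.

**Synthetic cohorts** (`generate_cohort()`, `cohort_config()`,
`default_feature_specs()`): seeded tables whose group means sit at
configurable standardized (Cohen's *d*) offsets per feature, with
within-modality correlation, optional outliers and detection-floor censoring
(`inject_contamination()`). Default effects use the published per-feature
values (e.g. striatal proportional volume *d* = −3.13 / −16%, globus
pallidus −2.00 / −22%, urinary p75 +1.71 / +44%).

## Worked example

```r
library(stabmark)

cohort <- generate_cohort(cohort_config(seed = 1))   # 50 mice x 27 features
fit <- analyze_features(cohort)
tidy(fit) |>
  dplyr::filter(feature == "vol_striatum") |>
  dplyr::select(contrast, test_used, p_raw, q_decision, cohens_d, percent_change)
#>       contrast test_used    p_raw q_decision cohens_d percent_change
#> 1     genotype anova_lsd 4.84e-13       TRUE    4.604         -16.86
#> 2    treatment anova_lsd 3.44e-09       TRUE   -2.718          13.98
#> 3 wt_treatment anova_lsd 2.56e-01      FALSE    0.546          -2.19
```

The striatal proportional volume is ~17% smaller in vehicle-treated R6/2
mice than in wild types (FDR-rejected, huge effect), and ~14% larger again
under treatment; the wild-type treatment control shows nothing — exactly the
structure the generator was calibrated to.

```r
res <- run_stability(cohort, classification_task("genotype"), "SVM-KNN",
                     n_permutations = 200, seed = 1, max_per_class = 13)
res
#> <stability_result> SVM-KNN on genotype task: 200 permutations, n/class = 12/13
#>   best mean accuracy 1.000 at k = 15

head(dplyr::arrange(res$occurrence, dplyr::desc(percent)), 5)
#>           feature percent
#> 1    vol_striatum   100.0
#> 2      vol_cortex   100.0
#> 3    vol_thalamus    93.5
#> 4 urinary_p75_ecd    89.0
#> 5 R2star_striatum    86.5
```

Genotype is separated essentially perfectly at 17–20 features, and the
features occurring most often among the top-15 predictors are the large-effect
volumetric, relaxometry and urinary markers. `autoplot(res)` draws the
accuracy/precision/recall curves, `plot_occurrence(res)` the occurrence heat
map. `run_pipeline(run_config(...))` chains generation, statistics and all
requested task/combo stability runs, and writes CSV/JSON artifacts.

```r
te <- default_echo_grid()                       # 3.5, 8.5, ..., 38.5 ms
fit_r2star_loglinear(te, 100 * exp(-0.026 * te), roi = "striatum")
#>        roi r2star  s0 fit_r2 n_echoes_used n_dropped
#> 1 striatum     26 100      1             8         0
```

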