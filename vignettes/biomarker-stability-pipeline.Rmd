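---
title: "Evaluating multi-modal biomarker panels with calibrated simulation and stability selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating multi-modal biomarker panels with calibrated simulation and stability selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stabmark)
library(dplyr)
```

# The problem

Preclinical trials in neurodegeneration increasingly measure many candidate
biomarkers at once — MRI volumetry, diffusion metrics, relaxometry, plasma
cytokines, urinary proteins — on cohorts of a few dozen animals arranged in a
2×2 genotype-by-treatment design (here: wild-type and R6/2 Huntington's-model
mice, each given vehicle or a p75 neurotrophin-receptor ligand, "C31" in the
group labels). Two questions follow. Univariately: which features separate
genotype, and which respond to treatment, with what effect size and power?
Multivariately: how well do *combinations* of features classify genotype or
treatment status, and which features are consistently informative when the
small cohort is repeatedly re-split?

`stabmark` implements that full analysis path as reusable, tested functions,
together with a synthetic-cohort generator calibrated so that its default
output has the statistical structure such studies report. Because the
generator is part of the package, every downstream procedure can be validated
against known ground truth.

# The synthetic cohort model

Each feature $f$ is parameterized by its WT-Veh baseline mean $\mu_f$, a
coefficient of variation $c_f$, and signed standardized shifts
$(d^{geno}_f, d^{trt}_f, d^{wt}_f)$. With common within-group SD
$\sigma_f = \mu_f c_f$, group means are

$$\mu_{f,\mathrm{WT\text{-}Veh}} = \mu_f,\qquad
  \mu_{f,\mathrm{R6/2\text{-}Veh}} = \mu_f + d^{geno}_f\sigma_f,\qquad
  \mu_{f,\mathrm{R6/2\text{-}C31}} = \mu_{f,\mathrm{R6/2\text{-}Veh}} + d^{trt}_f\sigma_f,$$

and analogously for WT-C31. Noise is Gaussian by default (group summaries in
this field are reported as mean ± s.e.m. and analyzed with parametric tests
first); a moment-matched log-normal option exists as a distributional
sensitivity check. Within each modality block (volumes, MD, FA, ODI, R2*,
cytokines) the noise terms share a compound-symmetric correlation
`correlation_rho` through a Gaussian copula; across modalities features are
independent. The default `correlation_rho = 0.2` encodes mild within-modality
coupling — no covariance information is available to calibrate it, so it was
fixed once at a value typical of within-modality ROI correlations and not
revisited.

## Calibration of the default panel

The default panel has 27 features: 6 proportional ROI volumes, 4 MD, 4 FA,
1 ODI, 5 R2*, 6 plasma cytokines, and urinary p75NTR-ecd. Where a published
standardized effect is available it is used verbatim (striatal proportional
volume $d = -3.13$, cortex $-3.66$, globus pallidus $-2.00$, corpus callosum
$-1.90$; striatal R2* $-2.57$, globus pallidus $-1.6$, cortex $-1.83$;
urinary p75 $+1.71$ genotype and $-0.68$ treatment; striatal FA treatment
$1.32$ toward wild type). Features without a printed value default to
$|d^{geno}| = 1.5$ and $|d^{trt}| = 1.0$, signed by the direction of the
reported group differences (volumes and ODI fall in R6/2, MD and cytokines
rise, striatal FA rises while other FA falls, raw R2* falls; treatment moves
R6/2-C31 toward wild type, except for features reported unresponsive, whose
$d^{trt} = 0$). The four rescued volumes have treatment effects reported only
as a range (0.97–2.00); fixed values inside that range were assigned per ROI
(striatum 2.00, cortex 1.50, globus pallidus 1.20, corpus callosum 0.97).

Coefficients of variation are the free scale parameters. For features where
both a percent change and an effect size are reported, the two pin the CV
exactly: a 16% striatal volume reduction at $d = 3.13$ forces
$c = 0.16/3.13 \approx 0.051$, and likewise cortex ($0.16/3.66$), globus
pallidus ($0.22/2.00$), corpus callosum ($0.09/1.90$) and urinary p75
($0.44/1.71 \approx 0.26$). Remaining CVs use field-typical values chosen
once: 5–8% for MRI-derived metrics, 30% for plasma cytokines. Default group
sizes are 12 / 8 / 14 / 16 (WT-Veh / WT-C31 / R6/2-Veh / R6/2-C31), the
imaging-cohort sizes.

```{r}
default_feature_specs() |>
  filter(feature %in% c("vol_striatum", "urinary_p75_ecd"))
```

Gross-error contamination is separate from generation:
`inject_contamination()` displaces a configurable fraction of cells by
exactly `outlier_scale` within-group SDs and censors values below per-feature
detection floors to missing, recording every perturbed cell as ground truth —
this is what lets the 2-SD outlier filter and the below-detection exclusion
rule be tested rather than assumed.

## What the generator does and does not emulate

It reproduces group means, standardized separations, within-modality
correlation, heteroscedastic-by-scale noise, outliers and assay floors at the
summary-measurement level. It does not simulate images, voxel noise,
segmentation error, tensor/NODDI model fitting, assay calibration curves, or
litter/batch structure; feature values enter at the level the statistical
analyses consume. Passing tests therefore validate the *procedures* under a
known, plausible data-generating process — they are not evidence about any
particular real cohort.

# The univariate pipeline

`analyze_features()` applies, per feature:

1. **2-SD outlier filter** (`remove_outliers_2sd()`): one pass per group,
   mean and SD from the full sample, the a-priori criterion; removals are
   logged, never iterated. The filter runs before the normality screen —
   the ordering is not dictated by the source conventions, so removal-first
   was fixed and documented.
2. **Normality screen** (`ks_normality()`): the Kolmogorov–Smirnov composite
   statistic with estimated mean/SD is anticonservative against tabulated KS
   quantiles, so the null is simulated (Lilliefors-style) with 10⁴ draws per
   sample size under a fixed internal seed, cached, making the whole analysis
   deterministic. Groups under n = 5 are flagged and treated as normal.
3. **Variance screen**: a two-group F ratio test at α = 0.05 on the contrast's
   groups — the simplest rule consistent with a two-group Welch dispatch.
4. **Test dispatch**: both groups normal and variances equal → one-way ANOVA
   over all four groups with Fisher's-LSD planned-contrast t tests on the
   pooled error df (with two groups this is exactly the pooled t-test);
   normal but unequal variances → Welch's t; either group non-normal →
   Mann–Whitney (exact null when the smaller group has n ≤ 8 without ties).
   Only the three planned contrasts are computed: WT-Veh vs R6/2-Veh,
   R6/2-Veh vs R6/2-C31, WT-Veh vs WT-C31.
5. **FDR**: the two-stage adaptive Benjamini–Krieger–Yekutieli step-up at
   q = 0.05, applied within families — one family per MRI metric modality,
   one for the cytokine panel; the single urinary p75 feature is not
   adjusted.
6. **Effect descriptors**: Cohen's d with pooled SD (first-named group minus
   second), post-hoc power from the noncentral t, and percent change with the
   first-named group as denominator.

```{r}
cohort <- suppressWarnings(generate_cohort(cohort_config(seed = 1)))
fit <- analyze_features(cohort)
tidy(fit) |>
  filter(contrast == "genotype", modality == "volume") |>
  select(feature, test_used, p_raw, q_decision, cohens_d, power_posthoc,
         percent_change)
```

# R2* relaxometry

`fit_r2star_loglinear()` fits the mono-exponential decay
$S(TE) = S_0 e^{-R_2^* TE}$ by unweighted OLS on $\log S$; the default echo
grid is 3.5 + 5k ms, k = 0..7. Unweighted log-linear fitting is the stated
estimator; weighted or magnitude-bias-corrected variants are out of scope.
Non-positive signals are dropped rather than floored (a floor biases the
slope), requiring at least three surviving echoes. The estimator is exact on
noiseless input for any rate in [0, 200] s⁻¹ and recovers rates within 2% at
SNR ≥ 50; bias grows when late echoes approach the noise floor.
`volume_corrected_r2star()` divides by ROI volume (homogeneous of degree −1),
which is how a raw R2* *decrease* in an atrophic region can become a
volume-corrected *increase* — the direction the iron-accumulation
interpretation expects.

# Stability selection

`run_stability()` implements the two-step resampling procedure. Per
permutation: a stratified split holds out 6 subjects per class (the remaining
6–7 per class train); the ranker — linear-SVM weight magnitudes (C = 1) or
gradient-boosting total split gain (100 rounds, depth 3, learning rate 0.3) —
orders all features on the training set; then the classifier
(inverse-distance-weighted 3-NN or a 200-tree random forest) is fitted on the
top-k features and scored on the held-out subjects for every k from the full
panel down to 2. Curves aggregate mean ± SD accuracy, precision and recall
per k over permutations (default 1000); the occurrence matrix reports, per
feature, the percentage of permutations in which it ranked in the top 15.

Design points that were genuinely open, and how they were fixed:

* **Elimination style.** "Importance ranking followed by recursive feature
  elimination" with a KNN classifier only parses if ranking happens once per
  permutation and the classifier is evaluated on nested top-k subsets — KNN
  has no importances to re-rank with. That single-shot reading is the
  default; classical refit-per-step RFE is available via
  `refit_per_step = TRUE`.
* **Occurrence counting** uses positions 1–15 of each permutation's ranking,
  independent of k, giving one number per feature per task/combo.
* **Standardization scope.** Features are z-scored over the full table before
  splitting by default, mirroring analysis of a pre-standardized table; this
  leaks test-set location/scale information, so `zscore_scope = "train"`
  restricts scaling to each training set. On the default cohort the two
  differ negligibly, but the train-only mode is the right choice when
  honest out-of-sample calibration matters.
* **Determinism.** Per-permutation seeds derive from the master seed by
  counter; ties in every ranking break by the table's feature order. Identical
  inputs reproduce curves and occurrence matrices bit-for-bit.
* **Class coding**: genotype task codes WT-Veh = 0, R6/2-Veh = 1; treatment
  codes R6/2-Veh = 0, R6/2-C31 = 1. `logistic_rank()` (ridge logistic
  regression, fixed unit penalty on the mean log-likelihood scale) keeps that
  convention, so positive coefficients mark features elevated in the class-1
  group.
* **Cohort size for classification.** Groups are capped at 13 subjects per
  class (`max_per_class`), the size at which the published analysis ran, by
  one seeded subsample before splitting.

```{r, eval = FALSE}
res <- run_stability(cohort, classification_task("genotype"), "SVM-KNN",
                     n_permutations = 200, seed = 1, max_per_class = 13)
autoplot(res)
plot_occurrence(res)
```

## Monte-Carlo design of the validation suite

Two subtleties surfaced while validating the resampling stage, both worth
recording because they change what a "±3σ" check means.

First, permutations of one cohort are not independent evidence about the
procedure: all splits reuse the same 26 subjects, so per-permutation
accuracies are correlated through whatever chance structure that cohort drew,
and conditional on a cohort the expected null accuracy is not exactly 0.5.
Calibration and expected-performance checks therefore average over
*independent cohorts* (with the permutation budget spread across them) and
use the between-cohort standard error. For the default genotype and treatment
cohorts the between-cohort SD of mean accuracy is ≈ 0.05 — large enough that
single-cohort estimates routinely swing several points around the expectation.

Second, the test sizes were chosen so the assertions are sharp but stable:
5 cohorts × 40 permutations for performance targets, 8–10 cohorts × 12–15
permutations for null calibration, 2000 replicates for effect-size and
percent-change recovery, 10⁴ null draws per sample size for the normality
test, 2×10⁵ simulated t-tests per point for power validation. These are the
problem sizes at which the relevant Monte-Carlo errors fall well inside each
assertion's tolerance.

# Numerical and degenerate-input conventions

* Zero-variance samples: the 2-SD filter removes nothing; LSD with zero MSE,
  Cohen's d with zero pooled SD, and correlation with a constant input raise
  errors rather than returning infinities.
* Negative generator draws for these positively supported assays are clipped
  to zero with a counted warning; at the default CVs and effects (all CVs
  ≤ 0.26, |d| ≤ 3.7) clipping is rare.
* Features missing in more than half the subjects are excluded with a logged
  reason, mirroring analytes measured below their assay's detection limit.
* Precision is defined as 0 when a test split receives no positive
  predictions (the balanced 6+6 split makes this rare).
* The adaptive FDR falls back to rejecting nothing when stage 1 rejects
  nothing and to rejecting everything when stage 1 rejects everything, per
  the two-stage definition.

# Known limitations

* Effect sizes not printed in the source material default to fixed
  magnitudes; the real per-feature effect spectrum is certainly more varied.
  All classification-performance statements are about the calibrated
  simulation, not about any animal cohort.
* Compound-symmetric within-modality correlation is a coarse model of
  inter-regional dependence; no cross-modality correlation is simulated even
  though, e.g., volumes and R2* are biologically coupled.
* The log-linear R2* fit ignores Rician magnitude bias; at the SNR of typical
  ROI-averaged decays this is negligible, at voxel level it would not be.
* The univariate dispatch applies normality/variance screens per contrast;
  pre-testing affects downstream error rates in ways the FDR stage does not
  model. This mirrors the analysis being reproduced rather than current
  best practice (which would fit one heteroscedastic model).
* With 12–13 subjects per class, stability-selection accuracies have wide
  sampling distributions; the package reports SDs across permutations, and
  conclusions should rest on the cohort-averaged estimates described above.
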