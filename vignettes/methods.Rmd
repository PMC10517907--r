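---
title: "Models and methods behind placentadwi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind placentadwi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(placentadwi)
```

placentadwi analyses multi-b-value placental diffusion-weighted MRI for
studies of small-for-gestational-age pregnancy outcomes. This vignette
explains the signal models, the fitting algorithms and their numerical
choices, the statistical machinery, and what the synthetic-data generator
does and does not emulate.

## Signal models

All fitters operate on a per-voxel decay curve `S(b)` sampled at the seven
protocol weightings b = 0, 50, 100, 150, 200, 500, 800 s/mm²
(`protocol_bvalues()`). Internal units are mm²/s for diffusivities and
fractions for `f`; `report_scale()` converts to the conventional reporting
scales (10⁻³ mm²/s, percent).

**Virtual MR elastography.** `compute_vmre()` evaluates
`μ_diff = α·ln(S_low/S_high) + β` per voxel, with `S_low` and `S_high` the
signals at b = 200 and 800 s/mm² and the liver-derived calibration α = −9.8,
β = 14 (kPa). Two consequences worth keeping in mind:

- Equal signals at the two key weightings give exactly β = 14 kPa; with
  α < 0 the stiffness decreases strictly as attenuation between the two
  weightings grows.
- μ_diff is *not* a function of the IVIM parameters alone in real tissue.
  Applying the calibration to signals generated from the biexponential
  model with published group-mean `f`, `D`, `D*` yields group means of
  roughly 4.89/4.47 kPa, noticeably below published empirical stiffness
  values near 5.5/4.9 kPa: measured stiffness carries information the
  diffusion fit does not. The cohort generator therefore treats μ_diff as
  its own per-subject quantity rather than deriving it from simulated
  signals (see below).

**Biexponential IVIM.** The fast (vascular) pool decays at rate `D + D*`,
so the fitted apparent diffusivity of any perfused voxel lies strictly
between `D` and `D + D*`. Two fitters are provided:

- `fit_ivim_segmented()` (default in `fit_volume()`): log-linear fit on
  b ≥ 200 s/mm² (where the fast pool has decayed to numerical zero) gives
  `D` and the tissue intercept; `f = 1 − intercept/S0` with `S0` the mean
  signal at the minimum b; `D*` by golden-section minimisation of the full-
  curve residual sum of squares with `f`, `D` fixed. The threshold matches
  the protocol's low/high split used by the stiffness calibration.
- `fit_ivim_full()`: bounded Levenberg–Marquardt refinement over all four
  parameters, initialised from the segmented fit. Deterministic — no
  multi-start, no randomness — and a fixed point at the truth on noise-free
  data.

Bounds bracket physiological placental values: `f ∈ [0, 1]`,
`D ∈ [10⁻⁵, 5×10⁻³]`, `D* ∈ [5×10⁻³, 0.5]` mm²/s. Degenerate cases are
decisions, not errors: a non-positive step-2 `f` declares the voxel
perfusion-free (`f = 0`, `D*` = NaN) since noise can push the intercept
above `S0`; a D*-objective that is flat across its whole range marks `D*`
unidentifiable; a voxel with any non-positive signal returns an all-NaN
unfit record so volume fitting continues past it.

**Stretched exponential.** Implemented as `S0·exp(−(b·DDC)^Alpha)`. The
alternative reading that raises the whole exponential to `Alpha` collapses
algebraically to a mono-exponential with rate `Alpha·DDC`, leaving `Alpha`
unidentifiable, so the standard form is the only defensible choice; it is
stated prominently here because printed renditions of this model are often
ambiguous about the parenthesisation. Fitting is bounded nonlinear least
squares with `Alpha ∈ [0.01, 1]`, `DDC ∈ [10⁻⁵, 10⁻²]` mm²/s, initialised
at the fitted ADC and `Alpha = 0.8`. Mono-exponential input drives `Alpha`
to its upper boundary, as it should.

**Recovery guarantees.** On noise-free forward signals at the seven
protocol b-values, every fitter recovers its generating parameters to
better than 0.1 % relative error (`D*` to 1 %, reflecting the weak
conditioning of the fast pool); scale (`S → cS`) and volume-order
permutations leave all fitted parameters unchanged. These invariants are
enforced in the test suite.

## ROI summaries and reader agreement

`roi_summary()` averages masked, non-NaN voxels (SD with n−1 denominator)
and reports failed-voxel counts. The default workflow fits voxelwise and
then averages the map — matching how stiffness means are extracted from
segmented placentas; fitting the ROI-averaged signal instead is available
by summarising the signal before calling a scalar fitter, and is closer to
some vendor workflows.

`icc()` computes single-measurement ICCs from the two-way ANOVA mean
squares. The study design this serves — two fixed readers, plus repeated
reads by one reader — does not pin down one ICC form, so the package
defaults to the conventional pairing: ICC(2,1) (two-way random effects,
absolute agreement) for inter-reader agreement, where systematic reader
offsets should count against agreement, and ICC(3,1) (two-way mixed,
consistency) for intra-reader repeatability, where a stable offset between
reads should not. Confidence intervals use the standard F-distribution
method with Satterthwaite degrees of freedom for the absolute-agreement
form. One subtlety: the textbook ordering "absolute ≤ consistency" holds
only when the between-rater mean square is at least the error mean square;
with raters that agree better than the noise level the inequality can
reverse slightly, which is why the test suite asserts it only under
simulated rater offsets. Agreement bands follow the inclusive convention
≥ 0.75 remarkable, 0.40–0.75 medium, < 0.40 poor.

## Cohort statistics

- **Group comparison** (`compare_groups()`): per-group Shapiro–Wilk at
  α = 0.05 gates between Welch's t-test and the Mann–Whitney U test;
  categorical 2×2 tables get Pearson chi-square with Yates continuity
  correction by default. The correction is a toggle because published
  clinical tables are not always consistent about it: of the worked
  contingency examples shipped in the tests, preterm delivery and delivery
  route match the Yates-corrected p-values while the neonatal-sex
  comparison matches the uncorrected one — the package surfaces this rather
  than silently resolving it.
- **Risk modelling** (`logistic_model()`, `select_risk_model()`):
  maximum-likelihood logistic regression with Wald intervals and
  `OR = exp(coefficient)`. Separation is flagged (glm's extreme-probability
  warning, or any |linear predictor| > 15) and the last stable iterate
  reported. Covariate entry follows the common clinical procedure:
  univariately significant parameters enter, then backward elimination on
  Wald p < 0.05. No multiple-testing correction is applied anywhere, by
  design, matching standard practice in this literature; interpret
  marginal p-values accordingly.
- **ROC** (`roc_analysis()`): empirical AUC via pROC with automatic
  orientation (AUC ≥ 0.5) unless fixed; DeLong 95 % CI by default, a
  seeded 2,000-resample stratified bootstrap as the alternative; the
  Youden-optimal cutoff with ties broken toward higher specificity.
  `binormal_auc()` provides the closed form Φ(Δμ/√(σ₁²+σ₂²)) used as an
  independent oracle against simulation.
- **Gestational-age correlation** (`ga_correlation()`): both Pearson and
  Spearman are first-class, with no package-level default beyond the
  argument order, because study write-ups frequently name one in the
  methods and the other in the results; callers should state their choice.

## The synthetic-data generator

The generator defines the study conditions the statistics are exercised
under:

- `simulate_cohort()` draws per-subject parameter vectors from per-group
  multivariate normals calibrated to published SGA group summaries
  (adverse n = 20: μ_diff 5.47 ± 0.68 kPa, f 23.56 ± 3.94 %, D
  1.55 ± 0.23, D* 161.13 ± 48.07, DDC 2.40 ± 0.49, ADC 2.34 ± 0.44 ×10⁻³
  mm²/s, Alpha 0.70 ± 0.04; non-adverse n = 40 analogously), plus clinical
  covariates (gestational age at MRI ~ N(33.42, 2.76²) vs N(34.25, 2.80²)
  weeks; birth weight ~ N(1797.5, 516.4²) vs N(2593.75, 327.8²) g;
  categorical proportions from the corresponding clinical table). Draws
  are truncated to physical ranges (f ∈ (0,100), Alpha ∈ (0,1], positive
  quantities positive) by rejection sampling — not clipping — so the
  distribution shape near a bound is preserved; infeasible specifications
  (acceptance < 1 %) error out.
- Between-parameter correlation defaults to the identity because the
  source summaries publish no covariance. This is the main reason the
  combined μ_diff + f model's published AUC near 0.9 is *not* reproducible
  from summaries alone: it depends on the unobserved μ_diff–f correlation.
  The correlation is an explicit knob for sensitivity analyses.
- μ_diff is drawn as its own parameter rather than computed from simulated
  signals, for the calibration-gap reason given above. Signal-level
  phantoms (`simulate_phantom()`) are the tool for fit-recovery questions:
  regions with known generating models, optional Gaussian (default σ = 2 %
  of S0, a typical placental DWI noise regime) or Rician noise, the latter
  reproducing the magnitude-image noise floor σ√(π/2) where true signal
  vanishes.
- `simulate_reader_pair()` implements the additive two-way model
  `rating = truth + rater bias + N(0, σ²)` underlying the ICC machinery,
  so variance-component limits are checkable exactly.

What passing tests on these data do **not** show: robustness to motion and
ghosting artifacts, partial-volume effects at the placental margin,
spatially correlated noise, gestational-age-dependent parameter drift, or
anatomically realistic ROI geometry — none of which the generator attempts.

## Problem sizes and determinism

The shipped tests and the acceptance script use: 2,000 simulated cohorts of
20 + 40 subjects for AUC means; 100,000 draws for generator calibration;
1,000 replicate voxels for the noisy-fit bias check; 3,000 subjects for
variance-component ICC limits; n = 10⁴–4×10⁴ for logistic recovery. All
randomness flows through explicit integer seeds; fitting contains no
randomness at all. Reruns of `run_pipeline()` with the same configuration
reproduce every output bit-for-bit, and the emitted `manifest.json` (seed,
configuration, package version) suffices to reproduce a run.

## Known limitations

- The vMRE calibration constants are liver-derived; their transfer to
  placenta is an assumption of the method, not something the package can
  validate.
- Sample-specific published quantities — odds ratios, empirical Youden
  cutoffs, reader-ICC magnitudes, the combined-model AUC — depend on
  unpublished subject-level data; the package reproduces the *procedures*
  and exercises them on synthetic cohorts instead of reproducing those
  numbers.
- No spatial regularisation, motion/eddy correction, registration or
  resampling: masks must share the DWI grid exactly.
- D* is weakly identified at clinical SNR; treat voxelwise D* maps as
  qualitative.
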