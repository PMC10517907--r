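# placentadwi

Quantitative analysis of multi-b-value placental diffusion-weighted MRI
(DWI), built for studies that ask whether placental stiffness and perfusion
measures can flag small-for-gestational-age (SGA) pregnancies at risk of
adverse neonatal outcomes. The package covers the whole chain: reading 4-D
DWI volumes and ROI masks, voxelwise model fitting, ROI summaries and
reader-agreement statistics, and the subject-level cohort statistics (group
comparison, logistic risk modelling, ROC analysis). Because patient-level
imaging in this setting is rarely shareable, a calibrated synthetic-data
generator produces signal-level phantoms with known ground truth and
parameter-level cohorts matching published group summaries.

## Models

For a voxel with signal `S(b)` at diffusion weighting `b` (s/mm²) and
`S0 = S(0)`:

- **Virtual MR elastography (vMRE).** A stiffness surrogate from the signal
  log-ratio at two key weightings, `μ_diff = α·ln(S_low/S_high) + β` (kPa),
  with liver-calibrated constants α = −9.8, β = 14 and
  `S_low = S(b=200)`, `S_high = S(b=800)`. Stronger attenuation (softer
  tissue) gives lower μ_diff.
- **Biexponential IVIM.**
  `S(b) = S0[(1−f)·e^(−b·D) + f·e^(−b·(D+D*))]`, separating tissue water
  diffusion (`D`) from microvascular pseudo-diffusion (`D*`) with perfusion
  fraction `f`. Fitted by a segmented algorithm (log-linear high-b fit for
  `D`, intercept for `f`, 1-D search for `D*`) optionally refined by bounded
  nonlinear least squares.
- **Stretched exponential.** `S(b) = S0·exp(−(b·DDC)^α)` with diffusion
  distribution coefficient `DDC` and heterogeneity index `Alpha ∈ (0, 1]`;
  `Alpha = 1` recovers the mono-exponential model.
- **Mono-exponential ADC.** `S(b) = S0·e^(−b·ADC)` by log-linear least
  squares over all b-values.

Downstream, ROI means per subject feed group comparisons (Shapiro–Wilk-gated
t / Mann–Whitney, Yates-corrected chi-square), multivariable logistic
regression with backward elimination, ROC/AUC with DeLong intervals and
Youden-optimal cutoffs, two-way ICC for reader agreement, and
gestational-age correlations.

## Worked example

```r
library(placentadwi)
b <- protocol_bvalues()                     # 0 50 100 150 200 500 800 s/mm^2

# forward-simulate one voxel with the adverse-group mean IVIM parameters
sig <- biexp_signal(f = 0.2356, D = 1.55e-3, Dstar = 161.13e-3, S0 = 1, bvalues = b)
fit <- fit_ivim_full(sig, b)
report_scale(coef(fit))
#>      f      D  Dstar
#>  23.56   1.55 161.13
compute_vmre(sig, b)
#> [1] 4.886                                  # kPa

# a synthetic 20-vs-40 cohort calibrated to the published group summaries
cohort <- simulate_cohort(seed = 1)
compare_groups(cohort, "mu_diff")
#> mu_diff: t test, statistic = 5.04, p = 1.084e-05
roc_analysis(cohort$mu_diff, cohort$group)
#> ROC: AUC = 0.825 (95% CI 0.715-0.935), cutoff = 5.06 (higher_is_positive),
#>      sens = 0.850, spec = 0.700
```

The fitted parameters come back on reporting scales (`f` in percent; `D`,
`D*` in 10⁻³ mm²/s), matching how such tables are printed. The ROC output
says that in this simulated cohort a stiffness cutoff of 5.06 kPa best
separates the groups, with higher stiffness indicating the adverse class.

`run_pipeline(run_config(seed = 1))` chains every stage (simulate → fit →
ROI → statistics) and writes CSV/JSON results plus a reproducibility
manifest to an output directory.

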