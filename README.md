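# geoassay

Error geography of trace-metal soil assay uncertainty.

Urban soil surveys measure trace metals (As, Cr, Co, Cu, Fe, Pb, Mn, Hg, Mo,
Ni, Rb, Se, Sr, Zn, Zr) by X-ray fluorescence, and every assay comes with an
analytical error standard deviation (ppm). Those per-sample errors have a
geography of their own: they correlate across metals, aggregate to census
tracts, carry weak positive spatial autocorrelation, and interact with
sampling design. `geoassay` is a toolkit for analysing that error geography
and for asking how three error sources — **measurement** (analytical assay
error), **sampling** (which soil samples happened to be drawn), and
**specification** (assuming the wrong error distribution family) — propagate
into multivariate and spatial summaries of a survey. For environmental
epidemiologists and exposure scientists, the question is whether mapped
contamination patterns survive the uncertainty baked into the assays.

The package implements, as composable tidyverse-style functions:

* **Three-parameter log-normal error models by rankit regression.** For
  errors `y` with offset `δ`, fit `LN(y + δ) = α + β Φ⁻¹[(r − 3/8)/(n + 1/4)] + ε`
  on the Blom normal scores of the ranks; `δ̂` minimizes `1 − R²` of that
  regression (the probability-plot correlation criterion). Back-transformed
  means/SDs, Kolmogorov–Smirnov and Anderson–Darling diagnostics, and
  Huber-M outlier percentages follow. (`fit_three_param_lognormal()`,
  `fit_assay_errors()`, `goodness_of_fit()`.)
* **Error-source simulators.** Log-normal analytical redraws, a census-tract
  tessellation-stratified bootstrap, gamma/beta/uniform misspecified
  covariate regressions with six-sigma rank-beta intervals for the uniform
  draws, and the two-step bootstrap-then-redraw mixture.
  (`draw_errors()`, `bootstrap_resample()`, `mixture_draw()`,
  `replicate_tract_errors()`.)
* **Factor-dimension stability.** Principal-component extraction and varimax
  rotation of the tract-by-metal error correlation structure, Tucker
  congruence alignment of replicated solutions, and mean/SD loading
  summaries with prominence flags. (`factor_solution()`, `align_factors()`,
  `replication_summary()`.)
* **Spatial statistics.** Moran coefficient and Geary ratio with
  randomization/normality standard errors and spectral extreme bounds, the
  pure SAR model `x = μ + ρW(x − μ) + ε` by maximum likelihood, and the
  variance inflation `σ̂²/σ̂²_adjusted` that positive ρ induces.
  (`moran_geary()`, `sar_fit()`, `sar_inflation_experiment()`,
  `variance_decomposition()`.)
* **Uncertainty-aware map classification.** Per-tract confidence intervals,
  a separability score for class breaks (non-overlap of the straddling
  intervals), exact dynamic-programming break optimization, and
  quantile/tertile baselines. (`tract_intervals()`, `optimize_breaks()`,
  `quantile_breaks()`.)
* **A synthetic survey generator** (`make_tessellation()`,
  `landscape_config()`, `generate_survey()`) that plants a known 15-metal,
  4-factor loading structure with SAR-autocorrelated tract scores and
  log-normal marginals, so the whole pipeline is testable end to end
  without restricted survey data.
* **One-call orchestration** via `experiment_config()` / `run_experiment()`,
  which emits the full set of analysis tables, plus a thin CLI at
  `inst/cli/geoassay.R`.

Fitted objects ship `tidy()`/`glance()` methods and `autoplot()` views.

## Worked example

```r
library(geoassay)

tess   <- make_tessellation(3, 19)                      # 57 tracts
survey <- generate_survey(tess, landscape_config(seed = 1))
fits   <- fit_assay_errors(survey)
fits[1:5, c("metal", "mean", "sd", "delta_hat", "ks", "pseudo_r2_t", "pseudo_r2_bt")]
#>   metal  mean    sd delta_hat     ks pseudo_r2_t pseudo_r2_bt
#> 1 As     15.2  7.13     -5.60 0.0711       0.983        0.885
#> 2 Cr    107.   8.58     59.3  0.0393       0.991        0.990
#> 3 Co    141.  14.1    1131.   0.0466       0.988        0.988
#> 4 Cu     55.3  4.78     18.7  0.0298       0.994        0.994
#> 5 Fe    376.  38.4  275321.   0.0513       0.988        0.988
```

Each row is one metal's error marginal: the offset `delta_hat` shifts the
log-normal support (negative for left-skewed-support metals such as As;
weakly identified, and legitimately very large, for nearly symmetric
marginals such as Fe, where the fit approaches its normal limit), `ks` is
the distance of the transformed values from normality, and the transformed
pseudo-R² near 0.99 says the rankit line describes the ordered errors
almost perfectly.

```r
tm  <- tract_average(survey, log = TRUE, delta = setNames(fits$delta_hat, fits$metal))
sol <- factor_solution(tm, k = 4)
sol
#> <factor_solution> 15 variables, k = 4
#> % variance: 42.9, 24.8, 19.3, 12.8

moran_geary(tm$As, spatial_weights(tess, "binary"))[, c("mc", "gr", "se_mc_randomization", "mc_max")]
#>       mc    gr se_mc_randomization mc_max
#> 1 0.0662 0.910              0.0738   1.04

sar_fit(scale(factor_scores(sol, tm)[, 2]), spatial_weights(tess, "row"))
#> <sar_fit> n = 57, rho = 0.265, sigma2 = 0.9825, sigma2_adjusted = 0.937 (inflation 4.8%)
```

The four rotated dimensions account for ~100% of the error variance (the
planted structure has high communalities), tract-level Moran coefficients
are positive and weak, and fitting the pure SAR model to a factor's scores
shows how its naive variance exceeds the spatially adjusted one — the
variance-inflation cost of ignoring autocorrelation.

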