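---
title: "Methods: modelling the error geography of soil assay surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling the error geography of soil assay surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`geoassay` analyses the *geography of analytical error* in multi-metal soil
surveys: per-sample assay error standard deviations (ppm) for 15 trace
metals, observed at point locations inside a tract tessellation. This
vignette is the package's own account of the models it fits, the
simulation machinery, the numerical choices made where the methodology was
genuinely open, and what the synthetic-data tests do and do not establish.

## 1. The three-parameter log-normal error model

Assay errors are positive and strongly right-skewed, which motivates a
log-normal description with a support offset. For a metal's errors
$y_1, \dots, y_n$ the model on the transformed scale is an
order-statistics (rankit) regression

$$\ln(y_o + \delta) = \alpha + \beta\,\Phi^{-1}\!\left[\frac{r_o - 3/8}{n + 1/4}\right] + \varepsilon_o,$$

where $r_o$ is the rank of $y_o$ (ties receive average ranks) and the
covariate is the Blom normal score of its plotting position. For a value
from outside the sample, the denominator becomes $n + 1 + 1/4$: the new
observation occupies one of $n+1$ slots. Back-transformation uses the
log-normal moment identities
$\hat y_o = -\hat\delta + e^{\hat\mu_o + \mathrm{MSE}/2}$ and
$\hat\sigma_{y_o} = \sqrt{e^{2\hat\mu_o + \mathrm{MSE}}\,(e^{\mathrm{MSE}} - 1)}$.
The classical presentation of the second expression is sometimes labelled a
standard deviation while printing the variance formula; the package takes
the square root.

**Estimating the offset.** $\hat\delta$ is found by a one-dimensional
search over $\delta > -\min(y)$. The search objective is *not* the raw
regression MSE: as $\delta \to \infty$, $\ln(y + \delta)$ flattens toward a
linear function of $y$ and its MSE shrinks to zero no matter how poor the
distributional fit, so a raw-MSE search degenerates to the upper bound.
The package instead minimizes $1 - R^2$ of the rankit regression — the
scale-free equivalent, identical in spirit to the probability-plot
correlation criterion for threshold estimation. A coarse grid concentrated
near the lower support bound brackets the optimum; golden-section
refinement follows, and the returned $\hat\delta$ is verified in tests to
be a local minimizer.

Two behaviours are worth knowing. First, for nearly symmetric marginals
(small $\beta$, hence skewness $\approx 3\beta$ small) the offset is
weakly identified: the fit approaches its normal limit and $\hat\delta$
can legitimately run to the (generous) upper search bound. This affects
only the reported offset, not downstream analyses, which use the monotone
transform $\ln(y + \hat\delta)$. Second, negative offsets are allowed
whenever $\min(y) + \hat\delta > 0$, and the fitter accepts negative $y$
for the same reason (useful for exact-construction tests).

**Diagnostics.** Kolmogorov–Smirnov and Anderson–Darling statistics
compare $\ln(y + \hat\delta)$ with a normal distribution whose moments are
estimated from those same transformed values. They are reported as
descriptive statistics: estimated parameters, no small-sample adjustment,
no p-values. The K-S statistic is the exact maximum gap between the
empirical and fitted CDFs; the A-D sum uses tail-stable log-probabilities.
Two pseudo-$R^2$ values are reported: the rankit regression $R^2$
(transformed scale) and the squared Pearson correlation between the data
and the back-transformed fitted values — the latter is this package's
concrete definition, since no standard one exists. Outlier percentages
come from a Huber M-estimate of location (tuning constant 1.345, tolerance
$10^{-8}$, via `MASS::huber`) with MAD scale; observations beyond 3
robust SDs are flagged.

## 2. The synthetic survey generator

No public multi-metal error survey of this kind exists, so the generator
*is* the study system. It plants:

* a rectangular grid tessellation (default $3 \times 19 = 57$ tracts) with
  queen contiguity — adjacency structure, not polygon shape, drives every
  statistic used, and queen is the conventional default;
* per-tract sample counts from a truncated Poisson (minimum 5, mean 58 by
  default, so $\approx 3300$ samples), emulating uneven real-survey
  coverage; locations uniform within tracts (the within-tract point
  process is not modelled);
* tract-level factor scores from a zero-mean SAR process per factor,
  $f = \rho W f + \eta$ with row-standardized queen weights, standardized
  to unit variance; defaults $\rho = (0.264, 0.435, 0.527, 0.484)$ —
  values typical of weak-to-moderate tract-level autocorrelation;
* per-sample latent errors $\Lambda_m f(\text{tract}) + \sqrt{\psi_m}\,e$,
  with a planted $15 \times 4$ simple-structure loading matrix
  (communality + uniqueness = 1 per metal) shipped as a plain-text
  fixture, covering four interpretable dimensions (an urban/traffic
  group, a fertilizer group, an As/Pb/Zn treatment-chemical group, and a
  geogenic Mo/Zr pair);
* log-normal marginals via $y = -\delta_m + \exp(\alpha_m + \beta_m
  \cdot \text{latent})$, with $(\delta, \alpha, \beta)$ moment-matched to
  reference per-metal means and SDs for urban XRF assay errors (fixture
  file); non-positive draws are regenerated (they essentially never occur
  at the default parameterization);
* assay values positively coupled to the transformed error on the log
  scale (`value_coupling`, default 0.5, plus independent noise) — real
  surveys show error sizes growing with observed values, and a linear
  log-scale coupling is the simplest mechanism with that property.

A single master seed drives derived substreams per stage (counts, scores,
noise, values, placement), so stages are independently reproducible.

**What the generator does not emulate.** Within-tract heterogeneity comes
only from the uniqueness terms: factor scores live at tract level. Real
surveys also carry point-level factor structure, detection-limit
censoring, instrument drift, and irregular tract geometry. Consequently,
passing tests establish that the *pipeline machinery* is correct under the
planted structure — not that real surveys behave this way. One visible
consequence: because communalities are high, within-tract variance is
small, and the tract-stratified bootstrap perturbs tract means only
mildly, while analytical redraws centred at rankit-fitted values carry a
small systematic tract-level bias (the rankit residuals of clustered data
are spatially structured). On this generator the bootstrap therefore
disperses tract means *more* than analytical redraws (as expected) while
analytical redraws displace factor loadings slightly more than the
bootstrap does — an honest property of the chosen simulation definitions,
visible in the stability experiment's distance table.

## 3. Error-source simulations

All sources operate on the transformed scale and aggregate to
tract-by-metal matrices of averaged $\ln(y + \hat\delta)$ (the scale the
factor analysis uses):

* **analytical** — per sample, $z \sim N(\hat\mu_i, \mathrm{MSE})$,
  back-transformed; the per-sample fitted log-normal conditional;
* **sampling** — tract-stratified bootstrap: within each tract,
  resample that tract's samples with replacement, preserving counts;
* **gamma / beta** — refit the regression with the misspecified covariate
  ($\ln[(r - 3/8)/(n - r + 5/8) + 1/4]$ and the logit
  $\ln[(r - 3/8)/(n - r + 5/8)]$ respectively), then redraw with the
  Normal-residual mechanism on the transformed scale. The printed form of
  the gamma covariate is typographically ambiguous; the parse adopted
  keeps its argument positive and degrades gracefully to the beta
  covariate. Draws reuse the residual mechanism rather than sampling
  fitted gamma/beta densities because the regressions, not a
  density-sampling recipe, are what the methodology defines;
* **uniform** — draw a plotting-position probability from the six-sigma
  rank interval $p_i \pm 3\sqrt{r(n-r+1)/[(n+2)(n+1/4)^2]}$ (the exact
  beta variance of an order-statistic probability, with the Blom-style
  denominator), push it through the fitted line, add no residual noise;
* **mixture** — bootstrap-resample the fitted values, then apply the
  analytical redraw to the resampled set; one shared resampling per
  replication across metals.

Draws that would back-transform non-positive are floored at $10^{-12}$
and counted; on the default generator the floor count is zero.

The uniform source is *tighter* than the log-normal source (its
variability comes only from narrow rank intervals), but under these
definitions the reduction is a factor of roughly 2–3 in replication SD,
not the orders-of-magnitude collapse sometimes reported for
interval-restricted draws; the tests assert the direction at ratio
< 0.75.

## 4. Factor dimensions and their stability

Extraction is by principal components of the correlation matrix — the
first $k = 4$ eigenvectors scaled by the square roots of their
eigenvalues — followed by Kaiser-normalized varimax (convergence
$10^{-8}$). Component-style extraction was chosen because the variance
percentages characteristic of this problem (four dimensions accounting
for $> 90\%$) are component-type magnitudes; principal-axis factoring
would shrink them. Columns are sign-aligned (positive column sums, so all
error variables correlate positively with their dimensions) and ordered
by percentage of variance.

Replicated solutions are aligned to a reference by maximizing total
absolute Tucker congruence over all $k!$ column permutations with sign
flips — exact assignment, deterministic, idempotent. Stability summaries
report element-wise mean and SD of aligned loadings, a prominence flag
(row-maximum $|\bar r| \ge$ threshold), and a per-metal dimension
assignment with unassigned metals marked `NA`. The default prominence
threshold is 0.49 — the smallest loading conventionally bolded as
prominent in this literature; the observed threshold (smallest prominent
$|\bar r|$) is reported alongside, since thresholds are dataset-relative.
Factor scores use the regression (Thomson) method, which requires a
non-singular correlation matrix (at least 16 tracts for 15 metals).

## 5. Spatial statistics

The Moran coefficient and Geary ratio use binary queen weights (the
classical index definitions); standard errors come from the standard
closed forms under both the normality and randomization nulls, the latter
validated against permutation SDs in the tests. Extreme attainable values
$\mathrm{MC}_{\max}$ and $\mathrm{GR}_{\min}$ are Rayleigh bounds of the
symmetrized (respectively Laplacian) weights on the subspace orthogonal
to the constant vector.

The pure SAR model $x = \mu + \rho W (x - \mu) + \varepsilon$ uses
row-standardized weights (required for the $\rho$ parameter space),
$\hat\mu$ = the sample mean (pure/intercept-only specification), and
profile maximum likelihood with the eigenvalue form of
$\ln|I - \rho W|$; since $W = D^{-1}B$ with symmetric binary $B$, the
spectrum is computed from the similar symmetric matrix
$D^{-1/2} B D^{-1/2}$ and is real. The naive variance is the
$n$-denominator sample variance; the adjusted (uninflated) variance is
the filtered-residual variance
$n^{-1}\lVert (I - \hat\rho W)(x - \bar x)\rVert^2$ — the chosen
interpretation of a spatially adjusted variance, sharing the naive
estimator's denominator so the inflation ratio is clean. Shapiro–Wilk
p-values are computed on the filtered residuals. Variance decomposition
across error sources is plain subtraction of named components from a
total, with negative residuals flagged (ambiguous decompositions) rather
than fatal.

At the simulation sizes used here (a 30×30 lattice, $\rho = 0.4$), the
expected inflation of the centered naive variance is
$\frac{1}{n}(\operatorname{tr} S - \mathbf{1}'S\mathbf{1}/n)$ with
$S = ((I-\rho W)'(I-\rho W))^{-1}$, about 8.6% — the package's
`sar_inflation_experiment()` reproduces this analytic value; inflation
grows steeply with $\rho$ and is larger on small irregular lattices.

## 6. Uncertainty-aware classification

Per-tract intervals are normal-theory, $v \pm z_{(1+\ell)/2}\,e$. The
separability of a class break is the interval Jaccard distance of the two
straddling intervals, $1 - \text{overlap}/\text{union}$: 0 for identical
intervals, 1 for disjoint ones, partial in between, invariant under joint
affine rescaling; degenerate point intervals score 0 when identical and 1
otherwise. This is the package's concrete definition of a separability
criterion — the published software this mimics does not state a formula.

Break optimization is exact dynamic programming over the sorted order:
the `"separability"` criterion maximizes mean per-break separability; the
`"combined"` criterion maximizes $w \cdot \mathrm{GVF} + (1 - w) \cdot$
mean separability with $w = 0.5$ by default, where GVF is the Jenks
goodness-of-variance fit $1 - \mathrm{SSW}/\mathrm{SST}$. Both terms are
additive over classes/breaks, so the DP is exact; ties break toward equal
class sizes (minimum sum of squared class sizes). The default map uses
$k = 5$ classes, with tertiles ($k = 3$ quantile breaks) as the baseline
scheme; massive ties trigger a logged fallback to distinct-value
quantiles.

## 7. Orchestration, problem sizes, reproducibility

`run_experiment()` chains the stages: generate → fit per metal →
reference factor solution → per-source replications (aligned, summarized,
propagated to MC/GR, SAR-fitted on averaged fields) → variance
decomposition → classification. Per-dataset SAR variance tables are
reported on the scale where the original factor scores have unit
variance, so source rows are directly comparable. The variance
decomposition uses, per factor, total = 1 and components = the variance
*lost* by each source's averaged field (1 − source $\sigma^2$), matching
the subtraction arithmetic of §5's table conventions.

Default problem sizes are the package's study conditions: 57 tracts,
$\approx 3300$ samples, 200 replications per error source (the
full-scale convention of $10^4$ replications is a config value; 200
replications already pin loading SDs to two decimals and keep the full
experiment in the minutes range). The test suite exercises the complete
chain at these sizes plus many reduced ones; every stochastic stage is
seeded, and identical seeds give bit-identical tables.

## 8. Known limitations

* The offset of a near-symmetric shifted log-normal is weakly identified;
  $\hat\delta$ is then reported at the search bound and should be read as
  "normal limit", not a physical support threshold.
* The separability formula and the combined objective's $w$ are this
  package's definitions; fidelity to any specific published
  implementation is not claimed.
* Tract polygons are unit squares; no CRS handling, no real census
  geography, no kriging or point-level geostatistics.
* The generator's within-tract structure (uniqueness only) understates
  real within-tract heterogeneity; bootstrap-vs-analytical comparisons on
  real surveys may order differently than on the synthetic default (see
  §2).
* K-S/A-D values are descriptive; no censored-data handling for
  below-detection-limit assays.
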