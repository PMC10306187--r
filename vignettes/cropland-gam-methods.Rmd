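---
title: "Spatio-temporal GAMs for rapid cropland-productivity monitoring: models and methods"
author: "cropgam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatio-temporal GAMs for rapid cropland-productivity monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Satellite estimates of cropland Gross Primary Productivity (GPP, gC/m² per
8-day composite) arrive as long gridded time series: hundreds of thousands to
millions of (pixel, date) observations over a country. Questions of interest
— has productivity trended up over a decade? did it drop after a disruption
such as the February 2022 invasion of Ukraine? — require separating three
confounded sources of variation: a repeating 12-month season, a slow
inter-annual trend, and persistent spatial structure, all on top of
temporally autocorrelated noise within each pixel. cropgam implements this
decomposition as a penalized-spline generalized additive model (GAM) with an
AR(1) residual correction, together with the downstream inference the
monitoring workflow needs: effect curves, uncertainty-mapped prediction
surfaces, a pre/post step-change test, validation statistics against annual
production tonnage, and zonal extraction of shipping route-density rasters
around ports.

## The two models

Writing \(z_i\) for GPP at row \(i\) with month \(m_i\), year \(y_i\) and
pixel location \(s_i = (\mathrm{lon}_i, \mathrm{lat}_i)\),

**Trend model** (`fit_trend_model()`):
\[
z_i \sim N(\mu_i, \varphi), \qquad
\mu_i = \beta + f_1(y_i) + f_2(m_i) + f_3(s_i) + f_4(y_i, m_i) + f_5(s_i, y_i).
\]

**Event model** (`fit_event_model()`): with \(w_i \in \{\text{pre},
\text{post}\}\) the disruption factor (treatment-coded, pre = reference,
the cutoff date itself counted as post),
\[
\mu_i = \beta + w_i + f_1(m_i \mid w_i) + f_2(s_i \mid w_i) + f_3(s_i, m_i \mid w_i),
\]
so every seasonal and spatial smooth may differ by period, and the factor
coefficient directly estimates the additive post-event step change in mean
GPP after that structure is absorbed.

### Smooth-term bases

* **Inter-annual trend** \(f_1(y)\): cardinal natural cubic regression
  spline, basis dimension equal to the number of unique years (each basis
  function is 1 at one knot, 0 at the others; knots at quantiles of the
  unique years), penalized by the integrated squared second derivative. The
  basis extends linearly beyond the knot range.
* **Season** \(f_2(m)\): cyclic cubic regression spline with basis dimension
  12 and evenly spaced knots over \([1, 13)\), period 12. Value, slope and
  curvature match at the December–January wrap by construction — the basis
  row at \(m\) and \(m + 12\) is identical to machine precision.
* **Space** \(f_3(s)\): low-rank Gaussian-process smooth with basis
  dimension 50. Knots are chosen by a greedy farthest-point design over the
  observed pixels, a Matérn(ν = 3/2) kernel is built at the knots and
  eigen-decomposed, and the data are projected onto the scaled knot
  eigenbasis (Nyström construction: features \(Z = K_{nk} U \Lambda^{-1}\),
  penalty \(\mathrm{diag}(1/\lambda_j)\), so the quadratic form approximates
  the GP prior \(f' K^{-1} f\)). Distances are great-circle kilometres by
  default; the kernel range defaults to half the maximum inter-pixel
  distance. A `"degrees"` mode reproduces fits on raw unprojected
  coordinates where required.
* **Interactions**: row-wise Kronecker tensor products of the marginal
  bases, one penalty (hence one smoothing parameter) per margin. The margins
  reuse the main-effect specifications, except that the spatial margin is
  rank-truncated to its 20 leading eigenpairs to keep interaction blocks
  modest; this rank is a configuration knob (`space_rank_tensor`) flagged
  for sensitivity analysis, since "same specification as the main effects"
  underdetermines the interaction ranks.

### Identifiability

Every smooth is centered by absorbing the sum-to-zero constraint (QR of the
column-sum vector), leaving the level to the intercept. Tensor interactions
are built from the *constrained* margins, which yields interaction-only
smooths that are identifiable next to the main effects with no further
constraint.

For the event model the by-factor copies are produced from the *globally*
centered smooth: rows outside a level are zeroed and penalties carried over
unchanged, with no re-centering within the level. This choice matters. The
post window (late February–December) does not cover the seasonal cycle
evenly, so the true seasonal curve has a nonzero mean over post rows.
Re-centering each copy over its own rows would force that window mean into
the factor coefficient, biasing the step estimate by
\(E[\text{season}\mid\text{post}] - E[\text{season}\mid\text{pre}]\) (about
+0.28 gC/m² at the default simulation conditions). With global centering the
penalty ties level to shape: each level's smooth carries its own window's
seasonal mean, and the factor coefficient estimates the pure step. The cost
is a near-confounded direction (a level shift on the post window is
representable only as a visibly wiggly curve), which the roughness penalty
resolves; its footprint shows up in the uncertainty discussion below.

## Estimation

Fitting is penalized least squares on the stacked design: Cholesky
factorization of \(X'WX + \sum_l \lambda_l S_l\), with a small ridge
(\(10^{-10}\,\mathrm{tr}(X'X)/p\)) fallback if the penalized system is
numerically singular, and an explicit rank check with named collinear
columns when all \(\lambda = 0\). Effective degrees of freedom are the trace
of the influence matrix, accumulated per term; \(\varphi = \mathrm{RSS}/(n -
\mathrm{edf})\).

**Smoothing parameters** maximize the Gaussian restricted likelihood with
the scale profiled out,
\[
-2\ell_r(\lambda) = (n - M_0)\bigl(\log 2\pi\hat\varphi + 1\bigr)
 + \log\lvert X'WX + S_\lambda \rvert - \log\lvert S_\lambda \rvert_+,
\]
where \(M_0\) counts unpenalized directions and \(\lvert\cdot\rvert_+\) is
the pseudo-determinant. The optimizer is L-BFGS-B in \(\log\lambda\) with
analytic gradients (envelope theorem for the penalized deviance; trace
identities for the determinants), multi-started from all smoothing
parameters at \(10^{-3}\), \(1\) and \(10^3\) and bounded in \([e^{-30},
e^{30}]\). Single-penalty log-pseudodeterminants reduce to \(r_j \log
\lambda_j + c_j\); tensor blocks (two penalties) are eigen-decomposed per
evaluation, which is cheap at their block sizes. GCV is available as an
alternative criterion flag; REML is the default because it is the standard,
better-behaved choice for Gaussian additive models and the reference
machinery for this class of model does not pin the criterion down.

**AR(1) errors.** One global correlation \(\rho\) is shared by all pixels.
The default estimator is the plug-in pooled lag-1 autocorrelation of the
independence-fit residuals within each pixel's date-ordered series (pixels
with fewer than 3 epochs are skipped); a golden-section search of the
whitened REML score over \(\rho \in (0, 0.99)\) is available where the extra
refits are affordable. The model is then refit on exactly whitened data —
first row of each pixel scaled by \(\sqrt{1-\rho^2}\), later rows \(r_t -
\rho r_{t-1}\) — so GLS under the AR(1) correlation reduces to OLS on the
transformed rows; smoothing parameters are re-selected on the whitened data
starting from the independence optimum. Note the plug-in targets the lag-1
correlation of the *total* residual; when white measurement noise overlays
an AR(1) process the estimate is the correspondingly attenuated correlation,
which is the right quantity for whitening the observed residuals.

**Step-change uncertainty.** Two covariances are kept. Smooth curves and
surfaces use the Bayesian posterior \(\varphi(X'WX + S_\lambda)^{-1}\),
standard for penalized smooths. The Wald test of the factor coefficient uses
the frequentist sampling covariance of the penalized estimator,
\(\varphi A^{-1} X'WX A^{-1}\): the near-confounded level direction
discussed above is ridge-stabilized, so its posterior spread substantially
overstates the sampling variability of the point estimate (measured on the
default synthetic conditions: posterior SE ≈ 0.025 versus replicate sd ≈
0.011, versus sampling SE ≈ 0.012). With the sampling covariance the
nominal 95% intervals cover the injected truth at close to (slightly above)
their nominal rate, which the acceptance suite checks across 50 replicates.

**Degrees of freedom** for the test are \(n - \mathrm{edf}\), with a normal
approximation beyond \(10^4\).

An optional covariate-binning flag rounds coordinates to a grid, aggregates
duplicated (pixel, month) rows and fits with frequency weights — a
simplified speed-up in the spirit of covariate discretization; it skips the
AR(1) stage (aggregated rows no longer form per-pixel series) and does not
promise bit-identical estimates, only agreement of the step estimate well
within its SE (tested at 0.5 SE).

## Inference outputs

* `effect_curve()` returns *summed effects*: intercept + the selected
  smooth evaluated over a covariate grid, other covariates fixed at training
  medians, the factor at the requested level (its coefficient included for
  the post level) — matching the usual additive-model plotting convention.
  SEs come from the posterior covariance via the delta method. Out-of-range
  grids warn and extrapolate linearly.
* `predict_surface()` evaluates the full linear predictor over a spatial
  grid, flags nodes outside the convex hull of training pixels, and (by
  default) attaches the 3×3 bivariate class: sample terciles of the
  estimates crossed with sample terciles of the SEs, `class = 3(se tercile
  − 1) + estimate tercile`, ties to the lower class, with a deterministic
  green-by-purple palette. Terciles are computed from the mapped sample
  itself, not from theoretical quantiles.
* `event_effect_test()` reports estimate, SE, t, df and the two-sided p at
  machine precision; any "< 0.001" formatting is left to the report layer.
* `annual_effect_series()` evaluates the year effect at the observed years;
  both the summed and the centered (intercept-free) series are returned,
  since either convention may be wanted for correlation against production.
  `validate_against_production()` runs Shapiro-Wilk on both series and the
  one-sided Pearson test (fixed to "greater": the scientific question is a
  positive association between modelled productivity and tonnage).

## Shipping module

`buffer_mean()` is deliberately primitive: the unweighted mean of raster
cells whose *centers* lie within a great-circle radius (default 20 km) of a
port, missing cells excluded, zero intersecting cells an error. No
partial-cell area weighting is attempted — at 1-km route-density resolution
the center-in test is within a cell of exact and is reproducible against a
brute-force per-cell distance scan, which the tests exploit. Distances are
haversine on a 6371.0088 km sphere. Cumulative sums restart each January;
`percent_change()` computes \(100 (c_b - c_a)/c_{\mathrm{ref}}\) with both
months defaulting to the last month present in *both* years, since the
source description of the month convention is self-contradictory (it mixes a
December comparison with an August reference while the data end in August);
both months are exposed as arguments.

## Synthetic data: what it does and does not emulate

`simulate_gpp()` generates value = spatial field (sum of Gaussian bumps on a
base level) + exactly periodic seasonal cosine + linear inter-annual trend +
optional seasonal-by-longitude interaction + step \(\delta\) from the cutoff
date + per-pixel AR(1) noise + white noise, and returns the truth as used.
The default desk-scale scene is 16 × 16 pixels observed twice a month over
2020–2022 (18,432 rows), seasonal amplitude 1.5 gC/m² peaking in June, base
level 2 gC/m², \(\delta = -0.247\) gC/m² at 2022-02-24, AR(1) \(\rho = 0.3\)
with marginal sd 0.35, white noise sd 0.5, seed 20230628. These sizes keep a
full event-model fit at a few seconds so that 20–50-replicate studies run in
minutes; the amplitudes put the step at roughly half a residual sd —
detectable but not trivial.

Step-recovery and coverage studies set the trend slope to zero: the event
model contains no year term, so a secular trend is structurally confounded
with the pre/post factor (the post window sits at the end of the record).
That is a property of the model being studied, not of the implementation,
and the matched condition isolates what the recovery studies are meant to
measure. The default slope for trend-model demonstrations is 0.05 gC/m²/yr.

What the generator does *not* emulate: cloud/QA gaps and irregular
compositing, non-Gaussian heavy-tailed residuals, spatially varying seasonal
phase, spatially correlated noise fields beyond the smooth mean, and
measurement scale factors. Passing tests therefore demonstrate correctness
of the estimation machinery under the model's own assumptions — not that
real MODIS-derived GPP satisfies those assumptions. Input values are assumed
already in gC/m²; any sensor scale factor is the caller's responsibility.

`simulate_shipping()` builds monthly rasters from Gaussian-ridge corridors
(port to a common offshore hub) plus port hotspots, a fixed month-of-year
activity profile shared across years, optional per-port-per-year scaling
(which makes cumulative-ratio arithmetic exact through the full extraction
pipeline) and blackout windows that zero a port's contribution.

## Numerical choices and degenerate inputs

* Pixel identity uses coordinates rounded to 1e-6 degrees; rows are sorted
  (pixel, date) before any AR(1) operation, and unordered series are an
  error rather than silently reordered.
* Penalty PSD tolerance: eigenvalues above \(-10^{-8}\) of the largest are
  accepted; GP eigenpairs below \(10^{-10}\) of the largest are dropped.
* Missing values are dropped at table construction (available composites
  only); an all-missing stack yields an empty table with a warning.
* Constant residuals make the AR(1) estimate undefined (error); single-level
  factors in `by_factor()` warn and return the block unchanged.
* The CRS penalty has a linear null space, so an infinite penalty leaves the
  best-fit line, not a constant — the documented infinite-penalty collapse
  to intercept(+factor) holds for the event model, whose centered cyclic,
  GP and tensor penalties are all positive definite.
* CSV round trips write doubles with `%.17g` and parse with strtod, which is
  bit-exact for finite values.
* All randomness flows through explicit seeds (default 20230628);
  re-running any generator or fit with the same seed and configuration is
  bit-identical.

## Known limitations

Gaussian response only; one global \(\rho\) (no per-pixel or seasonal
correlation structure); the spatial smooth models the mean, not a residual
spatial error field, so unmodelled spatial noise leaks into the scale; the
GP range is plugged in rather than profiled; binning is approximate by
design; and GPP itself is an imperfect proxy for harvested production
(harvest index, abandoned fields), which is exactly why the validation
module exists.
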