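# cropgam

Rapid monitoring of cropland productivity from satellite time series, for
analysts who need statistically defensible answers fast: has cropland Gross
Primary Productivity (GPP) trended up or down? did it drop after a
disruption — a war, a drought — and by how much, with what uncertainty? The
package implements the full analysis as reusable, tested components, plus a
shipping-activity module for monitoring the export side of the value chain,
and synthetic-data generators so everything is verifiable without satellite
downloads.

## The model

Gridded GPP observations `z_i` (gC/m² per 8-day composite) at month `m_i`,
year `y_i` and pixel location `s_i` are decomposed with a penalized
regression spline GAM:

    z_i ~ N(mu_i, phi)
    mu_i = b0 + f1(y_i) + f2(m_i) + f3(s_i) + f4(y_i, m_i) + f5(s_i, y_i)

with a cubic regression spline in year (basis dimension = number of years),
a cyclic cubic spline in month (dimension 12), a low-rank Gaussian-process
(Matérn 3/2, Nyström) smooth in space (dimension 50), and tensor-product
interactions. Smoothing parameters are selected by REML; residual temporal
dependence within each pixel is handled by estimating a global AR(1)
correlation from the residuals and refitting on exactly whitened data
(GLS = OLS after the transform).

For pre/post inference the year trend is replaced by a two-level factor `w`
(pre/post the disruption date, default 2022-02-24, cutoff counted as post)
with period-specific smooths:

    mu_i = b0 + w_i + f1(m_i | w_i) + f2(s_i | w_i) + f3(s_i, m_i | w_i)

so the coefficient of `w` directly estimates the additive step change in
mean GPP, tested with a Wald t statistic.

Downstream: summed effect curves with standard errors, prediction surfaces
with 3×3 bivariate tercile uncertainty classes for mapping, validation of
the annual effect series against crop-production tonnage (Shapiro–Wilk, then
a one-sided Pearson test), and 20 km port-buffer extraction of monthly
shipping route-density rasters with within-year cumulative sums and
year-on-year percent change.

## Worked example

```r
library(cropgam)

# synthetic scene at the default study conditions: 16 x 16 pixels,
# twice-monthly composites 2020-2022, a -0.247 gC/m2 step at 2022-02-24
sim <- simulate_gpp(sim_config(trend_slope = 0))
fit <- fit_event_model(sim$table)
print(fit)
#> cropgam event model: n = 18432, edf = 125.4, phi = 0.3605, rho = 0.097
#>   step change (post - pre): -0.2653 (SE 0.0122)
#>   per-term edf:
#>                           parametric              s(month, cyclic):warpre
#>                                 2.00                                10.48
#>             s(month, cyclic):warpost     s(longitude,latitude, gp):warpre
#>                                 8.43                                28.86
#>    s(longitude,latitude, gp):warpost  ti(longitude,latitude,month):warpre
#>                                23.75                                30.88
#> ti(longitude,latitude,month):warpost
#>                                21.03

tt <- event_effect_test(fit)
sprintf("step change: %.4f gC/m2 (SE %.4f), t = %.2f, p = %.3g",
        tt$estimate, tt$se, tt$t, tt$p)
#> "step change: -0.2653 gC/m2 (SE 0.0122), t = -21.66, p = 4.86e-104"
```

The injected truth is −0.247 gC/m²; across 20 replicate scenes the mean
estimate is −0.2414 (see the acceptance script below).

The `analysis/` directory holds the numbered pipeline drivers, each a thin
narrative script over the package functions, writing its tables under
`results/`:

1. `01_simulate.R` — generate the GPP scene and monthly shipping rasters
2. `02_fit_trend.R` — seasonal-trend decomposition, annual effect series
3. `03_event_effect.R` — pre/post step-change fit, test, curves, surfaces
4. `04_validate.R` — normality checks + one-sided correlation with a
   production series (11 years, so df = 9)
5. `05_shipping.R` — port-buffer extraction, cumulative sums, percent change

Stage 5 prints, for the default scenario (2022 activity scaled to 0.55× at
Odesa and 1.70× at the Danube delta, with a February–June blackout at
Mariupol):

```
 Constanta  2.224809e-06
    Danube  6.999955e+01
  Mariupol -8.675723e+01
     Odesa -4.500000e+01
```

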