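# phenosync

Warming springs do not shift every plant equally. Within a population,
individuals differ in how much accumulated warmth ("forcing") they need
before leaf-out or flowering, and in how strongly that requirement is
modulated by day length and winter chilling. When warm preseasons pull
events earlier — into shorter days and after milder winters — those
individual differences are amplified, and the population's phenological
synchrony (the standard deviation of event dates among its individuals)
degrades. `phenosync` is an R package for quantifying that process, for
ecologists working with long-term phenological observation networks,
gridded climate data, or twig-cutting chamber experiments.

## What it computes

**Drivers.** Degree-day forcing `DD(t0, t) = Σ max(T_d − 5, 0)`;
chilling hours in the 0–5 °C band from 1 November; photoperiod `DL(L,
DOY)` from the CBM day-length model with polar clamping; preseason
temperature (mean over the 60 days before the population's mean event
date); and the day a forcing requirement is fulfilled.

**Cleaning and pixelization** of PEP725-style observation tables:
series-level SD screen (> 25 days), 3 × MAD outlier screen (unscaled
MAD), 1° pixel assignment by coordinate floor, panel construction
(largest individual set sharing ≥ 15 common years, ≥ 3 individuals),
altitude screen (> 200 m from the panel mean) and ≥ 90 % yearly
coverage — in that fixed order, with an auditable removal log.

**Synchrony statistics.** Per pixel-year, the sample SD of event dates
(LOS/FLS, days) and of individual forcing sums (LOS-DD/FLS-DD,
degree-days); per pixel, OLS regressions of synchrony on preseason
temperature, chilling or photoperiod; across pixels, t-test summaries of
the correlation coefficients and a random-intercept distribution model
from which synchrony change is expressed as a percentage and as the
lengthening of the 95 % leaf-out window (`3.92 × ΔSD` days).

**Hierarchical Bayesian regression** of synchrony on drivers with
species and pixel random intercepts: `μ_i = α + β₁·temp_i + species_i +
pixel_i` (or day length + chilling jointly), N(0, 1000) priors on fixed
effects, Uniform(0, 100) on random-intercept variances, 2-SD
standardization for comparable effect sizes. The blocked Gibbs sampler
(RcppArmadillo) draws all location parameters jointly per sweep and
slice-samples the variances; convergence is checked with the
Gelman–Rubin statistic.

**Null model.** A degree-day-only simulation quantifies how much
synchrony loss follows from the spring temperature-curve shape alone
when individuals differ only in fixed forcing requirements.

**Twig experiments.** Per-individual forcing, day-length and chilling
requirements from chamber treatments; sequential-SS attribution of
leaf-out variation to the three cues; REML or moments variance
components (treatment / between-individual / within-individual).

**Synthetic data.** A seasonal + AR(1) climate generator (daily to
hourly) and a trait-based event simulator define reproducible study
conditions for all of the above; see the methods vignette
(`vignettes/phenosync-methods.Rmd`) for every default and its rationale.

## Worked example

Simulate one population through the full chain:

```r
library(phenosync)
clim    <- generate_temperature_series(climate_params(n_years = 20, seed = 42))
pop     <- population_spec(n_individuals = 12, seed = 43)
events  <- simulate_events(pop, clim)
cleaned <- pep_clean(events[!is.na(events$doy), ])
cleaned$log
#>    records_in      removed_series_sd   removed_mad_outliers
#>           228                      0                     29
#>  panels_built       removed_altitude removed_years_coverage
#>             1                      0                      2
#>    panels_out
#>             1

syn <- compute_synchrony(cleaned$panels[[1]], clim)
head(round(as.data.frame(syn), 2), 4)
#>   year n_obs sd_doy sd_dd mean_doy preseason_temp mean_chilling dl_at_forcing
#> 1 2002    12   4.62 24.02   117.92           3.38          2136         14.55
#> 2 2003    12   4.06 26.94   113.58           3.97          2208         14.29
#> 3 2004    12   5.62 28.81   105.50           5.45          2040         13.67
#> 4 2005    12   6.81 27.43   106.75           4.96          1968         13.69
```

Each row is a pixel-year: `sd_doy` is the leaf-out synchrony (days;
larger = less synchronous), `sd_dd` the spread of individual forcing
sums (degree-days), `preseason_temp` the 60-day pre-event mean
temperature. Warm years (2004–2005, ≈ 5 °C preseason) show earlier mean
dates and larger spread than cold years.

The multi-pixel pipeline aggregates this into the headline statistics:

```r
run <- run_all(run_config(seed = 7))
run
#> <phenosync_run> status=ok: 5 panels, 5 pixel regressions
#>   mean r = 0.164 (5 pixels, 100% focal sign)
#>   distribution-model slope = 0.138 [-0.062, 0.337] days/degC
round(run$hb_fit$summary, 3)
#>                       mean    sd   q2.5 q97.5  rhat
#> alpha               -0.010 0.445 -0.821 0.799 1.000
#> beta_preseason_temp  0.126 0.095 -0.058 0.311 1.000
#> sigma2               0.194 0.031  0.143 0.262 1.000
#> var_pixel            1.042 4.015  0.037 7.219 1.003
```

Every pixel shows a positive correlation between preseason temperature
and the SD of leaf-out dates (synchrony loss with warming); the
cross-pixel random-intercept model puts the slope at ≈ 0.14 days of SD
per °C for this 5-pixel, 20-year synthetic demo, and the standardized
hierarchical-model coefficient `beta_preseason_temp` points the same
way (Rhat ≈ 1 throughout). `synchrony_change_metrics()` converts a
fitted SD model into the percentage SD increase between a cold and a
warm preseason and the corresponding lengthening of the 95 % leaf-out
window in days.

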