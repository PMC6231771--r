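---
title: "Models and methods behind phenosync"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phenosync}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific question

Within a plant population, individuals do not leaf out or flower on the
same day. The spread of event dates among the individuals of a
population — phenological synchrony, measured as the standard deviation
of event dates in a pixel-year (LOS for leaf-out, FLS for flowering) —
matters for pollen exchange, herbivore pressure and competition. If
individuals differ in how their spring phenology responds to
temperature, day length and winter chilling, climate warming will not
shift all individuals equally: synchrony itself becomes a function of
temperature.

`phenosync` implements the full analysis chain needed to study this at
desk scale: environmental drivers, observational-data cleaning,
synchrony statistics, hierarchical Bayesian regression, a degree-day-only
null model, twig-experiment analytics, and a synthetic data generator
with the statistical structure the analysis assumes, so that every stage
is testable without restricted-access observational archives.

# Driver computations

**Forcing** is accumulated warmth: the degree-day sum
$\mathrm{DD}(t_0, t) = \sum_{d = t_0}^{t} \max(T_d - 5, 0)$ with base
temperature 5 °C and accumulation from 1 January for the observational
analysis (10 December for chamber experiments; the start is a
parameter). The printed growing-degree-day formula is sometimes written
without the clamp at zero; `phenosync` clamps negative increments, the
standard convention implied by calling 5 °C a *base* temperature.

**Chilling** is the number of hours between 1 November of the preceding
year and the event with mean temperature in [0, 5] °C. Each time step in
the band contributes its step length (a 6-hour step contributes 6), so
daily, 6-hourly and hourly series are handled uniformly; steps longer
than a day are rejected.

**Photoperiod** uses the CBM day-length model: orbit angle
$\theta = 0.2163108 + 2\arctan(0.9671396 \tan(0.0086\,(\mathrm{DOY}-186)))$,
declination $\phi = \arcsin(0.39795 \cos\theta)$, and
$\mathrm{DL} = 24 - \frac{24}{\pi}\arccos\!\big[\tfrac{\sin(0.8333\pi/180) +
\sin(L\pi/180)\sin\phi}{\cos(L\pi/180)\cos\phi}\big]$.
The constant 0.39795 is the sine of the Earth's axial tilt; the
inverse-cosine argument is clamped to $[-1, 1]$ so that polar day and
night return 24 h and 0 h instead of being undefined beyond the polar
circles. The test suite verifies agreement with an independent
implementation (`geosphere::daylength`) to $10^{-9}$ h.

**Preseason temperature** is the mean daily temperature over the 60 days
before the population's mean event date, excluding the event day itself.
The reference date is the long-term mean event date of the pixel — one
fixed window per pixel — because a window re-centred every year would
conflate date shifts with temperature sampling. A per-year window is
available behind a flag (`per_year_window = TRUE`) for sensitivity
analysis.

# Cleaning and pixelization

Observation series are cleaned in a fixed order, with strict
inequalities exactly as each rule is stated:

1. drop series whose across-year SD of the event day exceeds 25 days
   (erratic observers); a series with SD exactly 25 is kept;
2. drop observations deviating from their series median by more than
   3 × MAD, with the MAD unscaled (no 1.4826 factor) — read literally as
   the median absolute deviation. When the MAD is zero, any off-median
   value is removed (documented degenerate case). This screen is
   one-pass by design: it is applied once to the raw series, not
   iterated to a fixpoint;
3. assign 1° × 1° pixels by the floor of latitude and longitude (the
   grid origin is a convention; boundary coordinates belong to the pixel
   they index);
4. per (pixel, species, phase), keep the largest set of individuals
   sharing at least 15 common observation years (at least 3
   individuals). The selection rule is not fully determined by that
   statement; `phenosync` maximizes the number of retained individuals
   subject to the shared-years constraint, exhaustively for up to 12
   candidate series and greedily (dropping the series whose removal most
   enlarges the common-year set) above that;
5. drop individuals whose altitude deviates more than 200 m from the
   panel mean (single pass; exactly 200 m is kept);
6. drop years with less than 90% of individuals observed (exactly 90%
   is kept).

Series with fewer than two years pass the SD screen (their SD is
undefined) but cannot meet the shared-years requirement, so they never
reach a panel. After the altitude and coverage passes, panels are
re-checked against the minimum-individual and minimum-year thresholds.
Counts removed at each step are logged so a run can be audited.

# Synchrony statistics

For each retained panel year, synchrony is the sample SD (n − 1
denominator; within-pixel samples are small and the sample SD is the
conventional estimator) of (i) event dates (LOS/FLS, days) and (ii) the
individuals' degree-day sums at their own event (LOS-DD/FLS-DD,
degree-days). The second measure separates two explanations of widening
date spread: a flattening spring temperature curve stretches dates
without changing individual forcing requirements, whereas diverging
individual requirements widen both.

Per pixel, OLS regressions of synchrony on preseason temperature (or
chilling, or day length at forcing fulfilment) give a correlation,
slope and two-sided p-value from the t distribution with n − 2 df.
Across pixels, the mean correlation is tested against zero with a
two-sided one-sample t-test, and the percentage of pixels with the
focal sign (and significant at 0.05, two-sided, no multiple-testing
correction) is reported.

The cross-pixel "distribution model" regresses a response (mean date or
SD) on preseason temperature with a pixel random intercept, fitted with
the package's own Bayesian sampler on the raw scale; posterior means
serve as estimates. From a fitted SD model, the change between a cold
and a warm preseason is summarized as a percentage SD increase and as
the lengthening of the 95% leaf-out window, `3.92 × (SD_warm − SD_cold)`
days under a normal model of within-pixel dates (3.92 = 2 × 1.96; the
normal quantile is used rather than an empirical one because the model
describes the fitted distributions).

# The hierarchical Bayesian model

Synchrony values $y_i$ are modelled as normal with
$\mu_i = \alpha + \beta_1\,\mathrm{temp}_i + s_{species(i)} + u_{pixel(i)}$
(temperature variant) or
$\mu_i = \alpha + \beta_2\,\mathrm{DL}_i + \beta_3\,\mathrm{chill}_i +
s_{species(i)} + u_{pixel(i)}$ (cue variant), random intercepts
$s_j \sim N(0, \tau_s^2)$, $u_k \sim N(0, \tau_u^2)$. Priors: $N(0,
1000)$ on $\alpha$ and $\beta$; Uniform(0, 100) on the random-intercept
*variances* (taken literally as variances, not SDs). The residual
variance prior is not pinned down by the model statement; Uniform(0,
100) is used for uniformity. Continuous variables are standardized by
two sample SDs by default (mean 0, SD 0.5), which puts all coefficients
on a directly comparable effect-size scale; raw-scale fits are available
with `standardize = FALSE`.

A joint multivariate formulation with a correlation structure across the
four synchrony responses is sometimes written down but never specified
(form, prior, estimation), so each dependent variable is fitted in its
own univariate model.

**Sampling.** The sampler is a blocked Gibbs scheme written in C++
(RcppArmadillo). All location parameters — fixed effects and both sets
of random intercepts — are drawn *jointly* from their exact
multivariate-normal full conditional via one Cholesky factorization per
sweep. This removes the strong posterior correlation between the
intercept and the random-intercept means that makes single-site updates
mix slowly. The three variances have bounded-support conditionals
$\propto v^{-n/2} e^{-S/2v}$ on (0, 100); they are updated by shrinkage
slice sampling, which needs no tuning parameter. Chains are seeded
`seed + chain` and are exactly reproducible. The degenerate no-group
case (one species, one pixel) drops the random effects with a warning
and reduces to Bayesian linear regression, which matches OLS under these
diffuse priors; with no data at all the fixed effects sample their
prior, a property the tests use as a prior-predictive check.

**Convergence** is assessed with the Gelman–Rubin potential scale
reduction factor per parameter; any $\hat R > 1.1$ flags the fit as not
converged (a warning, never silent). Default chain lengths are 3 × 4,000
iterations with 1,000 burn-in — calibrated desk-scale settings whose
interval coverage the acceptance tests verify; production-scale lengths
(e.g. 3 × 200,000 with 50,000 burn-in) are plain arguments.

# The synthetic generator and what it does (not) emulate

The generator is the package's definition of the study conditions.

**Climate.** Daily temperature is a seasonal cosine (annual mean 9 °C,
half-amplitude 9.5 °C, warmest at DOY 200 — a Central European lowland
profile), plus a linear warming trend (0 by default), independent
year offsets (SD 1.2 °C, the scale of observed interannual spring
variability; an explicit offset vector can be supplied to impose a known
warming contrast), and AR(1) noise with stationary SD 2.5 °C and
autocorrelation 0.7 (realistic day-to-day persistence). Years have 365
days. Sub-daily resolutions add a sinusoidal diurnal cycle (half-range
4 °C) that averages to zero over each day, so chilling can be computed
at 6-hourly or hourly resolution without changing daily forcing.

**Individuals.** Each individual carries a base forcing requirement
$F_i$ (degree-days needed under 16-h days at a reference chilling of
1,800 h), a day-length sensitivity $g_i$ (DD per hour) and a chilling
sensitivity $c_i$ (DD per chilling hour), drawn from normal
distributions. Its event in a year is the first day $t$ with
$\mathrm{DD}(1\,\mathrm{Jan}, t) \ge \max\{F_i + g_i(\mathrm{DL}(t) - 16)
+ c_i(\mathrm{Ch}(t) - 1800),\ 10\}$. The additive-linear form is a
modelling choice: experiments report the cue responses as slopes at a
few treatment levels, which determines the local linear behaviour but
not the full functional form; linearity is the minimal model consistent
with slope-defined sensitivities, and the floor keeps the requirement
positive for extreme cue combinations.

Default trait scales are anchored on the beech twig experiments: the
population spans day-length slopes from about 0 (insensitive) to about
−27 DD/h — the documented range in which the most sensitive individual
needs more than twice the warming under 8-h as under 16-h days — with
mean −14 and SD 9; chilling slopes are small and homogeneous (mean
−0.10, SD 0.02 DD per chilling hour), matching the observation that
chilling requirements differ little among individuals; the base
requirement (mean 100, SD 20 DD from 1 January) places mean leaf-out in
late April under the default climate, where day length is near 14–15 h
and rising — the regime in which the day-length mechanism operates.
Under these conditions the simulated within-pixel SD is a few days and
the SD-versus-temperature slope a few tenths of a day per °C, the
magnitudes observed in long-term European records.

The generator deliberately omits: spatial correlation between pixels,
observation error in recorded dates, observer turnover within series,
frost damage, species differences (a single species label is emitted),
and real calendars (no leap days). Passing tests therefore demonstrate
that the *pipeline and statistics are correct under the assumed data
structure*, not that the assumed structure exhausts real observational
data.

A year is simulated only when the drivers it needs are covered: if any
chilling sensitivity is non-zero, years without the preceding 1 November
in the climate series are skipped. An individual-year whose requirement
is never reached by DOY 240 is emitted as an explicit missing flag, so
the coverage filter is exercised rather than bypassed.

# The degree-day-only null

Warming also flattens the spring temperature curve, which alone spreads
out the dates at which fixed, heterogeneous forcing requirements are
met. To quantify how much synchrony loss that mechanism explains,
`simulate_dd_only()` draws fixed requirements once (fixed individual
differences are the premise; per-year redrawing is an option), simulates
events from forcing alone, and regresses the per-year SD on preseason
temperature. On matched synthetic climates this null coefficient is
positive but substantially smaller than the coefficient produced by
heterogeneous day-length sensitivity, the package-level restatement of
the finding that curve flattening alone cannot explain observed
synchrony loss. The published null coefficients depend on a specific
station record and are not reproduced here; the package reports its own
coefficients on synthetic climates.

# Twig-experiment analytics

From chamber observations (replicate twigs per individual × collection
date × day-length treatment), per-individual traits are estimated as:
the forcing requirement = degree-days until leaf-out in the
long-chilling × 16-h cell; day-length sensitivity = OLS slope of
degree-days on treatment hours (8/12/16) at the last collection;
chilling sensitivity = OLS slope of degree-days on chilling hours at
collection, under 16-h days. Chilling treatments are encoded as
accumulated chilling hours at collection rather than calendar dates, so
the slope has physical units. Cell values average the first eight twigs
to leaf out; cells with fewer are averaged over what is available and
flagged.

Leaf-out variation across individuals is attributed to the three traits
by sequential (Type I) sums of squares in the fixed order forcing →
day length → chilling, per chilling level, expressed as percentages of
the total SS including the residual (summing to 100). The SS type and
order are conventions — they are not determined by reporting percentages
alone — so the order is an argument and the choice is logged; with
orthogonal predictors the order is irrelevant, which the tests exploit.

Variance components of the random-effects-only model (treatments, and
individuals nested within treatments) are estimated by REML (lme4) by
default, or by balanced expected-mean-squares moments (negative moment
estimates truncated at zero and flagged); the method is recorded in the
output. At the experiment's dimensions (11 individuals × 8 treatments ×
8 twigs) planted shares of 52/33/15 percent
(individual/treatment/residual) are recovered to within a few points in
median, which the acceptance tests verify.

# Numerical and design choices

* **Event resolution** is whole days (ceiling-day crossing), matching
  daily climate input; at constant temperature the event day is exactly
  $\lceil F/(T-5)\rceil$, a closed form the tests assert.
* **Ties and boundaries**: all cleaning thresholds are strict
  inequalities on removal; coverage uses ≥.
* **Degenerate inputs** raise typed conditions
  (`phenosync_invalid_parameter`, `phenosync_missing_data`,
  `phenosync_degenerate`) rather than returning silent NAs; unreached
  forcing requirements are NA *flags* by contract, not errors.
* **Seeding**: every stochastic function takes an explicit seed and is a
  pure function of (parameters, seed); the pipeline splits one global
  seed deterministically across pixels and stages.
* **Problem sizes**: the bundled demonstration and verification runs use
  5 pixels × 12 individuals × 20 years, 25-seed mechanism replicates,
  100 reduced-scale calibration fits (3 × 4,000 iterations) and 50
  variance-component simulations — sizes chosen so the whole suite
  re-runs in minutes on a laptop while keeping every statistical check
  at meaningful power.
* **Command-line interface**: the package is function-first, in the
  style of analysis packages in this field; `run_all()` plus
  `scripts/acceptance.R` provide the scripted entry points.

# Known limitations

The trait model is linear in its cues and ignores interactions between
chilling and photoperiod pathways. The pixel grid is a plain floor grid
without geodesic area correction. The MAD and altitude screens are
one-pass procedures whose re-application could in principle remove more
points; the pipeline applies them once, in the documented order. The
joint correlation structure across the four synchrony measures is not
estimated. Real observational data bring station heterogeneity,
observer effects and leap-year bookkeeping that the synthetic structure
does not emulate.
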