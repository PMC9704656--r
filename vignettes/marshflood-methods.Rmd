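---
title: "Methods: from tidal inundation to porewater nutrient trends"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from tidal inundation to porewater nutrient trends}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`marshflood` implements the analysis chain used by long-term salt marsh
monitoring programmes to ask whether sea-level-rise-driven changes in tidal
inundation are accompanied by changes in sediment porewater chemistry.
This vignette is the package's own account of the methods: the models and
their assumptions, the parameters that matter, the synthetic-data
calibration, and the numerical conventions that make results reproducible
bit for bit.

## Hydroperiod from water levels and plot elevations

The substrate of everything is a regularly sampled water-level series
(`water_level_series`) referenced to a named vertical datum, by default
NAVD88, with gaps kept as explicit missing values *on the grid*. Keeping
the grid dense makes data-coverage accounting exact and removes any
ambiguity about what a missing row means.

For a plot at elevation $z$, a sample with level $h_t$ is inundated iff
$h_t > z$. The conventions, chosen once and documented so that two runs of
the same data can never disagree:

- **Strict exceedance, ties dry.** Exact equality is measure-zero in real
  gauge data; counting ties as dry makes the monotonicity property
  (hours non-increasing in elevation) exact rather than almost-sure.
- **Each sample represents its own interval.** At 6-minute spacing each
  wet sample contributes 0.1 h; there is no interpolation of crossing
  times. This matches how an exceedance scan of verified gauge exports
  behaves and keeps the count a pure function of the samples.
- **Missing samples count as dry and break events.** Events are maximal
  runs of consecutive wet samples; runs are also split at calendar-year
  boundaries, so each annual summary is self-contained. The identity
  `n_events × mean_event_duration = hours_inundated` holds whenever there
  is at least one event.
- **Percent of year uses the full calendar year** (8760 h, 8784 h in leap
  years) as denominator, not the covered portion; coverage is reported
  separately, and a warning is raised when a year's coverage drops below
  95 %. Elevations are static across years, as in designs surveyed once.

Mean Higher High Water is the mean over tidal days (24.84 h, partitioned
from the epoch start; a partial trailing day is dropped) of each day's
highest water. In a semidiurnal regime the daily maximum *is* the higher
high water. The computation refuses to run below 90 % sample coverage
rather than return a biased datum.

Monthly mean sea level is the plain mean of non-missing samples per
calendar month. Seasonal adjustment subtracts each calendar month's
long-term mean and restores the grand mean. One subtlety is worth stating
because it cost an implementation iteration: for a record spanning whole
years, the climatology absorbs the *within-year* part of any linear trend,
so the adjusted series varies essentially year to year. The sea-level
trend is therefore regressed on calendar **year** as the continuous
predictor (`sea_level_trend()`); using a within-year-varying axis such as
decimal date would attenuate the recovered slope by
$\mathrm{var}(year)/(\mathrm{var}(year)+\mathrm{var}(month))$, about 0.8 %
for an 11-year monthly record.

## Plot-level rates of change

`fit_linear_trend()` is ordinary least squares of a response on a
continuous time axis, with a two-sided t test on the slope at
$\alpha = 0.05$ by default. The predictor is centred internally (the slope
is invariant to centring; the intercept is reported on the original
scale). Degenerate inputs are handled by convention rather than silently:
fewer than three pairs or a constant predictor is an error; a constant
response returns slope exactly 0, $R^2 = 0$ and a missing p-value.

Two different replication structures feed this fit, mirroring monitoring
practice:

- **Inundation**: the 11 annual totals of hours inundated, one per year
  (n = 11 per plot).
- **Porewater**: replicate samples are first averaged to plot-month means
  (`monthly_plot_means()`), and the four growing-season monthly means per
  year enter the regression as within-year replicates (n = 44 per plot for
  a complete record). This treats months as exchangeable replicates of the
  annual mean — acknowledged pseudo-replication, retained deliberately
  because it is the convention of the monitoring analyses this package
  reimplements. No multiple-testing correction is applied across plots for
  the same reason; the plot-level tests are descriptive filters for the
  rate grids, not confirmatory inference.

`rate_grid()` orders one trend per plot by segment, transect and position
from the forest edge and flags non-significant cells as masked. Masking
never alters a slope — a grid cell always carries its estimate plus a
visibility flag — so downstream consumers can reverse the filter.

## The zone × year mixed model

Per segment and nutrient, the model compares the first and last monitoring
years across marsh zones on plot-month mean concentrations:

$$\log c_{ijk} = \mu + \text{zone}_i + \text{year}_j +
(\text{zone} \times \text{year})_{ij} + b_{jk} + \varepsilon_{ijk}$$

with a single random intercept $b_{jk}$ for month $k$ nested within year
$j$ — one intercept per year-month cell — estimated by REML via
`nlme::lme`. With only two years in the contrast, a separate year random
intercept would be confounded with the fixed year effect; the nested cell
intercept is also what places the year test at the month-within-year
stratum under containment degrees of freedom (denominator
$2\times4 - 2 = 6$ for a complete two-year, four-month design), the
layout in which such analyses are conventionally reported. F tests are
sequential (Type I), the default of the fitting machinery. The natural log
is used, and non-positive concentrations are a hard error naming the
offending plot-months — no offset is silently added; in practice the
generator's detection floor keeps synthetic concentrations positive.

Marginal and conditional R² follow the Nakagawa decomposition
(`nakagawa_r2()`), with the fixed-effects variance taken as the variance
of the population-level predictions and negative variance-component
estimates truncated at zero first; conditional R² therefore never falls
below marginal R². The fixed-effects limit is testable: when the data are
constructed so the cell variance collapses to zero, the mixed-model F
statistics agree with a fixed-effects two-way ANOVA to better than one
part in $10^3$ (observed: ~$10^{-9}$).

## Rates on rates

The final stage regresses plot-level nutrient slopes (µM/yr) on plot-level
inundation slopes (h/yr per yr) across **all** plots, with no significance
filtering of either slope set — filtering would condition the sample on
the noise realisation and bias the relation. The two plot sets must match
exactly; anything else is an input error, not a join.

## The synthetic generator and its calibration

The generator defines the study conditions under which the package's
parameter-recovery claims hold.

**Tide** (`tide_config`): one semidiurnal constituent (amplitude 0.69 m,
period 12.42 h) approximating a south-east US Atlantic gauge's dominant
M2; an annual cycle of mean level (0.10 m, peaking in early autumn); a
linear mean-level trend of 13.2 mm/yr — the recent-decade rate the
defaults emulate; and iid Gaussian noise of 0.12 m standing in for the
meteorological residual at 6-minute spacing. The trend and seasonal terms
run on elapsed Julian years (365.25 d), so a configured rate of $r$ mm/yr
raises the level by exactly $r$ mm 365.25 days after the start — the
anchor for the trend-recovery tests. Timestamps are real calendar dates;
leap years are honoured wherever percent-of-year or monthly aggregation
is involved.

**Marsh** (`marsh_config`): two segments × three transects; Segment A has
nine plots per transect spanning 1.09 to −0.467 m NAVD88 with low, mid and
high zones, Segment B eight plots spanning 1.117 to −0.255 m with only low
and high zones (no mid-marsh mixed band), 51 plots in all. Elevations
descend linearly from forest edge to creek with Gaussian survey jitter of
sd 0.01 m — RTK-grade vertical noise — clamped to the segment range. Zones
are assigned from elevation against fixed boundaries (0.45 and 0.75 m in
Segment A; 0.75 m in Segment B), chosen so low-marsh plots sit below MHHW
(≈ 0.7–0.8 m under the default tide). Real programmes classify zones from
elevation *and* vegetation; a fixed threshold is the machine-reproducible
stand-in.

**Porewater** (`porewater_config`): for each plot, year $t$, month and
replicate,
$$c = b_{\text{zone}} + \gamma\, r \,(t - t_0) + m_{\text{month}} +
\varepsilon, \qquad \varepsilon \sim N(0, \sigma_{\text{zone}}^2),$$
truncated below at the detection floor (0.01 µM); salinity is analogous
with a common trend of −1.2 psu/yr instead of the coupling. $r$ is the
plot's inundation rate of change, supplied by
`default_inundation_rates()`: a linear decrease with elevation from
129.33 h/yr-per-yr at the lowest creekbank elevation to 7.25 at the
highest forest edge, the span of significant inundation trends such
transects exhibit. Additive Gaussian noise with floor truncation is the
simplest error model consistent with analysing rates on the untransformed
scale; a multiplicative model would be a non-default extension. Zone
baselines (NH₄ 55/20/10 µM, PO₄ 5/3/1.5 µM for low/mid/high) and noise
levels (NH₄ sd 25/10/5 µM) are set to the concentration ranges and spreads
low/mid/high marsh porewaters typically show; month effects are small,
zero-sum seasonal offsets so they cannot bias annual trends.

**Calibration.** The couplings default to
$\gamma = \text{target} / \bar r_{\text{low}}$, where
$\bar r_{\text{low}}$ is the mean design rate over low-marsh plots of the
nominal jitter-free layout (86.18 h/yr-per-yr) and the targets are the
mean low-marsh rates the defaults are calibrated to reproduce: 8.96 µM/yr
for NH₄ and 0.86 µM/yr for PO₄. This makes "mean recovered low-marsh
slope" a quantity with a known configured truth. The recovery harnesses
use distinct seed streams for the layout jitter and the chemistry noise;
a shared stream would correlate the plot truths with the measurement
errors and bias the mean recovered rate (observed: ≈ −0.05 µM/yr).

**What the generator does *not* emulate** — and hence what passing tests
do and do not show: no spatial autocorrelation between plots, no
autocorrelated measurement error, no wrack disturbance or vegetation
dynamics, no groundwater or tidal-pumping physics, no storm surges, and a
purely linear concentration response. Recovery of the configured rates
demonstrates that the estimation chain is unbiased under its own
assumptions; it does not validate those assumptions against field data.

## Reproducibility and numerical conventions

- Every stochastic function takes an integer seed and is bit-reproducible
  under it; `run_pipeline()` derives per-stage seeds from one master seed
  and writes a manifest with MD5 checksums of every output, so a rerun can
  be verified byte for byte.
- CSV readers parse numeric columns through base R's correctly rounded
  string-to-double conversion; the fast parser of the CSV engine can be
  one ulp off, which would break the guarantee that every reader/writer
  pair is an exact inverse on valid files.
- Readers never silently drop rows: duplicate keys, off-grid or
  non-monotone timestamps, unknown zone labels and negative concentrations
  are errors naming the first offender. Absent water-level rows become
  missing markers on the grid.
- Timestamps are naive local standard time on a monotone axis (stored
  internally as UTC, never converted between zones), the convention of
  gauge exports.

## Validation problem sizes

The shipped test-suite exercises: exact equivalence of the hydroperiod
engine against a sample-by-sample counter on 100 random gapped series of
up to 10⁴ samples plus analytic constant/sinusoid cases; elevation
monotonicity across all 51 plots over a full 11-year 6-minute record
(~964k samples); agreement of every OLS stage with closed-form
normal-equation oracles to 10⁻¹⁰; the mixed model's fixed-effects limit to
10⁻³; recovery of the calibrated 8.96 and 0.86 µM/yr low-marsh rates over
100 replicate datasets and of the 13.2 mm/yr sea-level trend over 20
replicate records, each within three standard errors of the replicate
mean; and a 5 % type-I error calibration over 1020 null plot-level tests.

## Known limitations

- The containment degrees of freedom and sequential tests are one
  convention among several (Satterthwaite or Kenward–Roger
  approximations would differ); they are used here because they are the
  reporting convention of the monitoring literature this package serves.
- The within-year replicate treatment of monthly means understates
  plot-level slope uncertainty when months are seasonally structured.
- MHHW uses a fixed 24.84-h partition anchored at the epoch start rather
  than the full tidal-datum epoch machinery of a national service.
- The porewater error model is additive Gaussian with floor truncation;
  strongly skewed concentration errors would call for the multiplicative
  alternative.
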