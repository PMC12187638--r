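---
title: "Models and methods behind nestherm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nestherm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`nestherm` quantifies how nest-site microclimate constrains the outside-nest
activity of a central-place foraging ectotherm, and what that constraint does
to colony effort and growth over years. This vignette explains each model,
its assumptions and tunable parameters, the synthetic generator the test
suite validates against, and the numerical choices made where the design was
genuinely open.

## 1. Thermal performance curves

Hourly worker counts on a trail are zero-inflated: either no workers are out
at all, or some number is moving. We therefore use a hurdle model with two
additive parts sharing the same covariate structure:

* presence: `count > 0` modelled as binomial with
  `logit p = β₀ + f(T) + b_nest`;
* abundance: the strictly positive counts modelled as Poisson with
  `log μ = γ₀ + g(T) + b'_nest`.

`f` and `g` are penalized cubic regression splines with basis dimension
`k = 5` (knots at quantiles, sum-to-zero constrained, second-order curvature
penalty), enough to express a unimodal thermal response without chasing
hour-to-hour noise; `b_nest` are nest-ID random intercepts absorbing nest
idiosyncrasies (colony temperament, resource quality of the destination
tree). Smoothing parameters and random-effect variances are selected by
REML; the fitting engine is `mgcv::gam`, wrapped behind `fit_additive()`
which also reports per-term effective degrees of freedom (EDF), deviance
explained, AIC, and an EDF-based BIC (`−2ℓ + EDF·log n`), the only coherent
dimension measure for penalized fits.

The **combined curve** `C(T) = p(T)·μ(T)` is the activity measure used for
all window extraction; predictions exclude the random effects (a
population-typical nest) and, in *adjusted* mode — which adds a parametric
nest-size term and a time-of-day smooth — are benchmarked to the median nest
size and noon. The Poisson part is fitted untruncated, a deliberate
approximation for positive counts whose means are well above zero near the
peak; `truncated = TRUE` applies the `μ/(1 − e^(−μ))` correction when
combining. Swarm (defence) activity, measured as a speed, is a plain
Gaussian additive model with the same temperature smooth and random
intercept.

Window definitions and their numerical conventions:

* **Peak**: argmax of `C` on a regular grid (default 0.1 °C) over the
  observed temperature range; ties break toward the lower temperature for
  determinism; a peak at the range edge is flagged and no optimal window is
  computed for it (a fraction-of-apex window is undefined without an
  interior apex).
* **Optimal window** (`fraction = 0.90` by default): the maximal contiguous
  grid interval containing the peak on which `C ≥ fraction · C(peak)`.
* **Emergence window**: by default the observed range (min and max
  temperature across active observations); a model-based variant returns the
  temperatures where fitted presence probability crosses 0.5. Both are
  offered because observed extremes and model crossings answer slightly
  different questions; the observed range is the default as the more
  conservative, assumption-free reading.

When upper-tail data are too sparse for modelling, the upper threshold is
bracketed empirically: *liberal* = the maximum temperature at which workers
still emerged; *conservative* = the median temperature of non-emergence
observations.

## 2. Emergence change-point model

The lower threshold at which swarming begins is estimated by a hierarchical
two-segment model: speed is zero-mean noise below a nest-specific threshold
`τ_j` and rises linearly above it,

```
y_i ~ Normal(β · max(0, T_i − τ_j(i)), σ²),   τ_j ~ Normal(μ_τ, σ_τ²).
```

Priors are weakly informative and range-respecting: `μ_τ` uniform over the
observed temperature range, `σ_τ` and `σ` half-Cauchy (scales 2 and 5 °C),
`β ~ N(0, 100²)`. Sampling is Metropolis-within-Gibbs: a conjugate Gibbs
draw for `β`, adaptive random-walk updates (tuned only during warmup, so the
post-warmup chain is a fixed-kernel Markov chain) for `τ_j`, `μ_τ`, and the
log-scale variance parameters. Defaults are 2 chains × 1000 warmup + 2000
draws; split-R̂ and an autocorrelation-based effective sample size are
reported per parameter, and runs should be accepted only with R̂ < 1.05.
When no observation falls below any nest's fitted threshold the object is
flagged `prior_dominated`: the threshold then rests on linear extrapolation
and, because the population-mean prior is bounded by the observed range, the
population summary can pile against the range edge.

## 3. Daily budgets from logger series

Logger series (default cadence 30 min) are reduced per nest-day. Daytime is
defined by positive solar elevation from a longitude-free local-clock
approximation (solar noon at 12:00, cosine declination); latitudes beyond
±66.5° are rejected since polar day/night breaks the day/night dichotomy.
Daily *minimum, maximum and range* use daytime samples only (the minimum is
the dawn temperature); a day is *complete* when observed daytime intervals
reach 90% (configurable) of the count expected from the cadence, and
incomplete days are excluded from model fits by default — logger gaps come
from battery failures and displaced probes, not from the weather, so
exclusion is ignorable.

*Available hours* for a temperature window `[lo, hi]` count observed
intervals with `lo ≤ T ≤ hi` (inclusive at both ends: the thresholds are
temperatures at which activity was actually observed) over the **full 24-h
day** — night temperatures fall below `lo` and contribute zero naturally —
times the cadence in hours. A daytime-only scope is available as a switch.
Missing intervals contribute zero and the day keeps its completeness flag.
Per-nest seasonal summaries (the apex and base of a cyclic-spline trend
through daily hours) feed the compensation analysis.

## 4. Among-nest variance models and the RLRT

Daily responses are fitted with a cyclic cubic spline of day-of-year
(`k = 8`, knots joined at the year boundary) under three random-effect
structures: none, nest intercepts, nest intercepts + slopes. The slope
covariate is the *seasonal index* `cos(2π(doy − 15)/365.25)` (+1 mid-summer,
−1 mid-winter in the southern hemisphere), so a random slope lets the
summer–winter contrast differ among nests; the data themselves do not name a
slope variable, and the seasonal index is the natural one-dimensional
summary of the fixed trend. Models are ranked by the EDF-based BIC.

The variance components are then tested with a **refit-based parametric
bootstrap RLRT**: statistic `max(0, 2(ℓ_alt − ℓ_null))` on restricted
likelihoods; null responses simulated as conditional fitted values (spline
and any conditioned BLUPs included) plus iid Gaussian noise at the REML
scale; both models refitted per replicate; p-value `(1 + #{sim ≥ obs})/(n_sim
+ 1)`. Because the alternative differs from the null by exactly one
variance component, the refits can be made exact and cheap: smoothing
parameters of shared terms are estimated once from the observed data and
held fixed, the shared covariance is folded into a whitened projection, and
the tested component's restricted-likelihood profile reduces to the
eigenvalues of the projected random-effect cross-product. A refit then
costs microseconds, so the default `n_sim = 199` for exploration and
10,000-replicate confirmatory runs are both practical. Under the boundary
null roughly half the simulated statistics are exactly zero, as expected
from the chi-bar-square mixture.

Two calibration facts the test suite pins down: under data generated from
the null model itself the empirical size at α = 0.05 sits inside
[0.03, 0.07]; on daily temperature *ranges* — a right-skewed response,
being a max-minus-min — the Gaussian bootstrap runs mildly conservative
(size below nominal, never above). Conservatism on skewed responses errs
toward fewer false claims of among-nest differences and is the acceptable
direction; users wanting exactness there should transform the response.

## 5. Effort standardization, compensation, growth

Foraging effort is indexed by the yearly count of foraging plus tree trails
(connection trails excluded by default — they link nests rather than food —
with a switch to include them). Counts are log10-transformed and modelled
with `lme4::lmer` as `log10(trails) ~ size + (1 + size | nest)`, size
centred at the population mean; each nest's coefficient — its prediction at
the population-mean size, the only back-transformable size-free scalar — is
back-transformed via `10^x` into a standardized trail count. lme4 is used
here rather than the spline engine because the model is a plain random-slope
regression and per-nest coefficient extraction is direct. Zero-trail
nest-years cannot enter a log10 response and are dropped with a warning
(`log10(x + 1)` offered behind a flag).

The compensation analysis reports ordinary least-squares slopes and
t-values of (a) mean nest size and (b) standardized trails against summer
and winter available hours, with no decision rule imposed: under
compensation, size should be flat in hours while effort rises as hours
shrink; a positive size trend with no effort response indicates failure to
compensate. Degenerate predictors (zero variance in hours) are reported as
such rather than fitted.

Growth is assessed per nest by intercept-only, linear and quadratic
least-squares fits of entrance holes on years since first survey (centring
stabilizes the quadratic term), ranked by AICc with the parameter count
including the residual variance. Models whose correction is undefined
(`n − k − 1 ≤ 0`, i.e. quadratic below 6 years, linear below 5) are omitted
with a notice; constant series, whose likelihoods are unbounded, select the
no-change model by construction. Any model within 2 AICc units of the best
is flagged as supported, and t-values carry direction and magnitude.

## 6. The synthetic generator

The generator provides ground truth for every stage and defines the
conditions the test suite certifies.

* **Microclimate**: shared baseline `base_temp + base_seasonal_amplitude ·
  seasonal_index(doy)` (defaults 10 ± 7 °C — mid-latitude New South Wales
  dawn temperatures), plus a nest-specific half-sine bump between sunrise
  and sunset with amplitude `exposure_amplitude + seasonal_amplitude ·
  seasonal_index` (defaults spanning 12–24 ± 6 °C from sheltered to exposed
  placements), plus AR(1) noise on the logger grid (sd 1.5 °C,
  autocorrelation 0.8 — loggers fluctuate smoothly). Because the bump is
  daylight-only, all nests share an identical pre-dawn minimum each day
  while daytime ranges order by exposure, the qualitative signature of
  shade-differentiated nests that cool to a common overnight temperature.
  The half-sine gives closed-form oracles (maximum at solar noon equals
  baseline + amplitude; time-in-window has an arcsine expression).
* **Activity**: hourly dawn-to-dusk sampling on one mid-summer and one
  mid-winter day. Presence is a double logistic in temperature (midpoints
  17 / 42 °C, steepness 0.8 /°C), abundance Poisson with mean
  `20 · exp(−(T − 30)²/(2·5²))` scaled by `exp(0.04 · (holes − 30))`; swarm
  speeds are Gaussian around the same unimodal shape. These values put the
  generating peak at 30 °C and the emergence range near 16–43 °C, i.e. the
  magnitudes a field census of this system produces.
* **Surveys**: yearly entrance-hole counts under flat, linear
  (−2.5 holes/yr) or quadratic (+4 t − 0.6 t², growth-then-decline) trends
  with noise sd = 10% of mean size, and trail counts
  `10^(0.15 + 0.01·holes + propensity + ε)` with known per-nest offsets.
* **Swarm onset**: the two-segment change-point process itself (τ = 13 ±
  0.5 °C across nests, slope 1, σ = 1.5) for sampler validation.

What the generator does **not** emulate — and hence what passing tests do
not certify about field data: weather systems (shared day-to-day
deviations), humidity, heat waves and asymmetric diurnal curves, logger
drift, observer error in counts, spatial correlation or competition between
nests, and drought-driven regime shifts in the survey trends. Results on
real data inherit the usual caveats of the component models instead.

## 7. Problem sizes and reproducibility

All generators restore the global RNG state and are byte-reproducible from
their seed; the pipeline (`run_pipeline()`) drives every stochastic stage
from one config seed. The test suite certifies, among others: peak recovery
within 1 °C in ≥ 90% of 100 census-scale samples (237 observations, 11
nests); the 90% window of an exact Gaussian curve (sd 3 °C) matching its
closed-form half-width `3·sqrt(−2 ln 0.9) ≈ 1.377 °C` at 0.1 °C grid
resolution; exact agreement of interval counting with a brute-force loop on
1,000 random days; RLRT size within [0.03, 0.07] at 500 × 199 replicates;
growth-model recovery ≥ 80% over 210 ten-year series; change-point recovery
within 1 °C with ≥ 90% interval coverage over 50 seeds; and effort-offset
rank correlation ≥ 0.9 over 50 seeds. Simulation sizes (four-to-six-month
calibration series, 199 inner RLRT replicates, 1,500-draw MCMC) were chosen
as the smallest designs at which the binomial noise of the certified rates
is comfortably inside the asserted bands.

## 8. Known limitations

* The RLRT conditions on the shared smoothing parameters of the null fit;
  this is the standard conditioning used by fast RLRT implementations but
  ignores smoothing-parameter uncertainty.
* The untruncated Poisson hurdle part slightly overstates the conditional
  mean when means are near zero; the truncation flag exists for sensitivity
  checks.
* The solar model ignores longitude and the equation of time (minutes-level
  error in sunrise/sunset), which is immaterial at 30-min cadence.
* The change-point model assumes a common slope and Gaussian noise; speeds
  near zero are weakly non-Gaussian by construction.
* Single-nest inputs degrade gracefully (random-effect models are skipped
  with a notice) but among-nest questions are then undefined.
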