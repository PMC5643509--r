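---
title: "Detecting and modelling uniparental incubation from continuous nest monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and modelling uniparental incubation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(unicub)
```

## The problem

Biparentally incubating shorebirds alternate incubation bouts between
the female and the male, jointly achieving near-continuous nest
attendance. When one parent disappears — death, desertion, or an
experimental removal — the remaining bird faces a choice: give up, or
incubate alone. Continuous biologging records (nest temperature,
surface temperature next to the nest, and RFID detections of tagged
parents at a nominal 5-s cadence) let us detect such solo phases,
quantify the attendance rhythm the single parent keeps, and ask whether
solo-incubated clutches can hatch. `unicub` packages that analysis end
to end, with a synthetic-data generator providing ground truth for
every stage.

## From temperature to incubation state

A sitting parent holds the nest cup well above ambient; a bare nest
relaxes toward ambient exponentially. The classifier therefore uses
two signals:

* **margin rule** — a reading is incubation-like when
  `nest_temp − baseline ≥ margin_c`, where the baseline is a rolling
  median of the surface probe over `surface_window_min`
  (default 3 °C over 10 min). With `steep_slope_c_min = Inf` this
  per-reading threshold *is* the classification — a pure, trivially
  auditable rule used by the oracle tests.
* **slope hysteresis** (default) — the margin rule alone misclassifies
  the cooling tail after a departure: with a 20-min time constant and a
  30 °C excess, the nest stays ≥ 3 °C above ambient for roughly
  `τ·log(ΔT/margin) ≈ 46` min. So with `steep_slope_c_min` finite
  (default 0.5 °C/min on a `smooth_window_min` rolling mean) the state
  machine switches **off** on a steep negative slope or a margin
  failure, and **on** on a steep positive slope (arrivals re-warm the
  cup quickly) or on margin with non-negative slope. The last trigger
  wins; the initial state is the first reading's margin verdict.

Smoothing delays transition detection by up to one window; the tests
assert transitions within one `smooth_window` of truth on noisy square
waves, and *exact* truth recovery with smoothing disabled on noise-free
synthetic data.

Parent identity comes from RFID: each reading takes the sex of the
nearest detection within `rfid_window_min` (default 2 min). Bouts are
maximal incubated runs; off-gaps shorter than `recess_tolerance_min`
(default 60 min) are merged when the flanking parent is compatible, and
a change of attributed parent always splits — a clean change-over with
no off-gap still yields two bouts. Bout labels are majority-by-readings
with ties going to the earlier detection; unlabelled bouts are
`unknown`. All daily statistics use local solar time
(`UTC + longitude·24/360` h) with days delimited at local-solar
midnight; the sites span Alaska to Chukotka, so civil time zones would
misplace the thermal "night".

## The uniparental phase rule

Let `m` be the population's median incubation bout (hours). A maximal
same-sex run of bouts is a *solo span*; its onset is the partner's
final failure to return. The first `m` hours after the onset are the
remaining parent's "regular" bout — the bird is likely still unaware —
and are excluded. The remainder qualifies as a uniparental phase iff it
is at least `qualify_multiple · m` long (default 2, so the whole span
is ≥ 3 m).

The defining sentence admits a weaker reading (total span ≥ 2 m,
i.e. remainder ≥ m). We adopt the stricter reading and expose it as a
single parameter, because it keeps the *reported* phase itself at least
twice the median bout, consistent with the stated intent of excluding
one prolonged bout caused by the partner's absence; `qualify_multiple`
flips to the other reading in one place if a user disagrees.

Additional rules:

* **hatching trims** — a phase may not overlap the 6 h before hatch
  start nor the 24 h before chicks were found; the qualification test
  is applied *after* trimming, so the retained data are pure
  uniparental incubation.
* **causes** — a removal event before the onset ⇒
  `experimental-removal`; a capture within 24 h before the onset ⇒
  `post-capture` (the attribution window is a parameter; the source
  study reports the category without one); the partner returning to
  alternate after the phase ⇒ `temporal`; otherwise
  `natural/unknown`. Priority in that order.
* **censoring** — if the recording ends while the solo span is still
  running (and the end was not set by a hatching trim), the phase is
  flagged censored: its duration is a lower bound. Nests where only one
  parent was ever observed from the first reading are a censored-start
  variant of the same situation; they enter the phase table like any
  solo run but their onset is the recording start, not an observed
  departure.
* **span boundaries** come from sex-labelled bouts only: isolated
  unknown-sex blips (noise artifacts after a full desertion) must not
  stretch a span.
* phases with `unknown` sex are retained in counts but excluded from
  sex-specific models.

Phase metrics: `start_fraction = 100·(start − incubation_start)/T`
with `T` the species' typical incubation period in days — values above
100 % legitimately mark desertions after the expected hatch date;
negative values are flagged anomalies. The incubation start itself is
estimated by a precedence ladder: observed start; laying rule
(`first_egg + clutch_size − 1` days, one egg per day and incubation
from clutch completion); hatch date minus `T`; an egg-flotation
stage→elapsed-days lookup (the underlying ageing regression is out of
scope, so the lookup is user-configurable); and finally the population
median of other nests' starts.

## Attendance and its purity filter

Attendance (incubation constancy) is the percentage of readings
classified incubated within a local-solar day or hour. Each reading
carries an incubation type — biparental, uniparental-in-biparental
species (inside a detected phase), or uniparental species (by the
reference flag) — and a window contributes a record only for a type
covering ≥ 75 % of its readings (boundary inclusive), computed on that
type's readings only. Denominators count *readings*, not elapsed time:
the original description does not say which was used, and reading
counts make sensor gaps shrink numerator and denominator symmetrically.
Hatching trims are applied before windows are formed, single-egg nests
and dislocated-probe spans are excluded. Hourly records carry
`sine`/`cosine` of `2π·hour/24` (evaluated at the window midpoint;
daily records carry local noon) so circular time enters the models
linearly.

## Models and uncertainty

All models are fitted by maximum likelihood with lme4:

* daily: `attendance ~ day_fraction * inc_type`,
* hourly: `attendance ~ (sine + cosine) * inc_type`,

each with random intercepts for nest and species *crossed with a
two-level biparental/uniparental factor* — encoded as composite
grouping factors `nest:type2` and `species:type2`, since the original
specification of "nest and species in interaction with incubation
type" does not pin down an lme4 formula — and the time covariate as a
random slope. Slopes are correlated with their intercepts by default
(the original is silent on this; `correlated_slopes = FALSE` switches
to independent terms). Sex-specific daily/hourly variants use the
uniparental records only. Hatching success is a binomial-logit mixed
model on one row per uniparental nest (start fraction, duration, median
daily attendance; species random intercept), with pairwise predictor
correlations reported and (quasi-)complete separation detected and
flagged — flagged rather than silently penalised, since no penalised
mixed solver is among the package's dependencies.

Uncertainty is summarised the way the `sim`-style literature does: the
posterior under a flat prior is approximated by `n_draws = 5000` draws
from `N(β̂, V̂)`, the multivariate-normal sampling distribution of the
fixed effects, reported as the median and the 2.5/97.5 percentiles.
This is not MCMC; for the sample sizes involved the normal
approximation is the established practice the package mirrors.
Variance components are reported as percentage shares
`100·σ²ᵢ / Σσ²ⱼ` over all random terms plus the residual, summing to
100 by construction.

## What the generator emulates — and what it does not

Defaults describe an arctic biparental sandpiper population: 20-day
incubation period, 11-h median bouts (log-normal, log-sd 0.25 — only
medians are published, and log-normality keeps positivity and right
skew), 5-min change-over gaps, a 5 ± 7 °C diel ambient sinusoid
(coldest at 02:00 local solar; an amplitude of 0 gives the polar-summer
no-darkness option), 35 °C incubated nest temperature, exponential
relaxation with 20-min cooling and 5-min warming constants, Gaussian
sensor noise (1.5 °C ambient, 0.8 °C attended), 0.9 per-reading RFID
detection probability, and desertions (probability 0.5 by default,
female in 80 % of cases, matching the observed sex bias) targeted
uniformly at days 5–15 and executed at the end of the deserting
parent's bout. The remaining parent then keeps a uniparental rhythm:
within each hour it is off for
`base_off + rate·warmth(hour)` of the hour (warmth 0 at the coldest
hour, 1 twelve hours later), producing the characteristic continuous
night attendance with midday recesses; the solo phase lasts a
log-normal median 3 days (the published case median) unless hatching
intervenes.

Not emulated: thermodynamically realistic egg temperatures, predation
events in the time series (predation exists only as an outcome label),
weather, probe dislocation, and re-nesting. A green test on synthetic
data therefore establishes that the algorithms implement their rules
correctly and recover known truth under the stated noise model — not
that the defaults reproduce any particular field dataset. The published
real-data coefficients (e.g. the −5.7 % sex difference or the
7/35/47/53/8 % variance shares) require the original raw deposit and
are deliberately *not* acceptance values; the packaged fixture pins
only the body-text count statistics (27 % hatched, 65 % deserted, 7 %
depredated, 80 % male, 17 % of nests, 10 % late starts).

## Numerical choices and edge cases

* Interchange files are CSV with ISO-8601 UTC timestamps at 1-s
  resolution; round-trip identity is tested. Missing sensor readings
  are kept as gaps at load time — interpolation is an extraction-level
  policy, and the extraction deliberately does none (gap readings
  simply drop out of both purity and attendance denominators).
* Validation is total: a file either loads fully or every offending row
  is reported with table, nest and reason.
* Bout-label ties (equal detection counts) go to the earlier-detected
  tag — deterministic by construction.
* `weighted_median` uses the cumulative-weight-½ convention with
  midpoint averaging at exact halves, reducing to the sample median at
  unit weights.
* Per-nest simulation seeds derive from the master seed by a fixed
  affine map mod 2³¹−1, so datasets are reproducible nest by nest.
* The empty-phase table, header-only inputs, all-identical outcomes
  (separation), single-level grouping factors, and out-of-range hours
  or longitudes all raise typed, informative errors or flagged results
  rather than propagating silently.

## Known limitations

* The slope/threshold defaults of the extraction are calibrated on the
  synthetic generator, not on the original field recordings, whose
  extraction constants are unpublished; they are exposed parameters.
* Signal-strength-based incubation inference for radio-tagged species
  is out of scope; such nests enter as precomputed state series.
* The capture-attribution window (24 h) and the recess tolerance
  (60 min) are documented conventions, not published values.
* With heavy sensor noise the hysteresis classifier can emit isolated
  false bouts; phase detection is shielded (span boundaries from
  sex-known bouts), but bout-level statistics on very noisy traces
  deserve inspection via `render_actogram()`.
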