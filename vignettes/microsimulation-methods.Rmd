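---
title: "Methods: a three-state microsimulation of air-pollution health impacts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a three-state microsimulation of air-pollution health impacts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microhia)
```

## The model

`microhia` simulates every resident of a set of small areas (census units of
roughly 1500 people, as in the UK's LSOA geography) through an annual-cycle
health-state-transition model with three states for a single chronic disease,
here parameterized for ischaemic heart disease (IHD):

* **H1** — free of diagnosed disease;
* **H2** — ever diagnosed (prevalent); absorbing until death, i.e. the model
  allows no return to H1 even though treated disease may become asymptomatic;
* **H3** — dead from any cause; terminal, and dead individuals take no
  further part in any calculation.

Each simulated year, every alive individual undergoes sequential Bernoulli
trials. An H1 individual first faces an incidence trial on `P(I|H1)`; if it
fires, the individual is diagnosed and faces the diseased-state mortality
trial `P(M|H2)` in the same year (a configurable choice, see *Numerical and
convention choices*), otherwise the healthy-state mortality trial
`P(M_~IHD|H1)`. An H2 individual faces only `P(M|H2)`. Survivors age by one
year after the trials. Stay-in-state probabilities are the complements of the
transition probabilities.

## From published rates to transition probabilities

National statistics report four population-level annual quantities per
age band and sex, each per 100,000 of the *total* population: disease
incidence, disease prevalence, disease-specific mortality and all-cause
mortality. Dividing by 100,000 gives the population probabilities `P(I)`,
`P(H2)`, `P(M_IHD)` and `P(M_All-cause)` (the direct quotient, not
`1 - exp(-r)`; at these magnitudes the difference is far below every other
uncertainty, and the annual Bernoulli cycle consumes plain annual
probabilities).

The three state-conditional probabilities follow from conditional-probability
identities under two assumptions: non-disease mortality is the same in H1 and
H2, and disease-specific death occurs only from the prevalent state:

* `P(I|H1) = P(I) / (1 - P(H2))` — incidence concentrated on the at-risk
  pool;
* `P(M_~IHD|H1) = P(M_~IHD) = P(M_All-cause) - P(M_IHD)` — the subtraction
  is performed *after* relative-risk adjustment of both terms, so mortality
  multipliers are never double counted;
* `P(M|H2) = P(M_IHD) / P(H2) + P(M_~IHD)` — the disease hazard concentrated
  on the prevalent pool plus the shared other-cause hazard.

An exact consequence, used as a standing test invariant, is that the adjusted
all-cause probability is reconstructed by the prevalence-weighted mixture:
`P(H2)·P(M|H2) + (1 - P(H2))·P(M_~IHD) = P(M_All-cause)` (pre-clamping).

The prevalence in the `P(M|H2)` denominator is the *baseline table*
prevalence of the stratum, not the evolving simulated prevalence: the case
fatality it encodes is derived from published cross-sectional statistics, and
making the transition matrix depend on simulated state occupancy would change
the estimand in a way the underlying statistics cannot support.

## Relative risks

**Exposure–response.** A per-10-µg/m³ relative risk `RR` is scaled to an
area's annual-mean PM2.5 `x` against the national population-weighted mean
`µ` as `RR^((x − µ)/10)`, so the multiplier is exactly 1 at the national
mean, multiplicative over concentration increments, and log-linear in `x`.
Defaults: 1.08 (incidence), 1.21 (case fatality), 1.06 (all-cause mortality)
per 10 µg/m³. The value of `µ` is a required configuration input with
default 10 µg/m³, an approximate UK urban-era population-weighted level; all
analytic constants reported by the package depend only on `x − µ`.

**Deprivation.** Mortality is additionally multiplied by
`ratio^((5.5 − j)/9)` for an area in deprivation decile `j` (1 = most
deprived), where `ratio` is the sex-specific most-to-least-deprived mortality
ratio (1.7 for men, 1.5 for women). Centring at the mean decile 5.5 makes
the geometric mean across deciles exactly 1, so the adjustment redistributes
risk without changing the population-average level. It applies to all-cause
and disease-specific mortality — before their subtraction — but never to
incidence, for which there is no comparable empirical support.

## Cessation lags

A reduction in PM2.5 does not deliver its full mortality benefit at once.
The package models this as a cumulative fraction `f(t)` of the asymptotic
benefit, applied by interpolating the *concentration* seen by each mortality
channel: `x_eff(t) = x_base − f(t)·(x_base − x_scenario)`. Because the
exposure–response is exponential, interpolating the concentration is exactly
linear interpolation of the log relative risk, the form used in life-table
practice.

* All-cause mortality uses the regulatory staged curve: 30% of the benefit
  in year 1, 50% spread uniformly over years 2–5 (0.125/year), 20% uniformly
  over years 6–20 (0.2/15 per year). The published tranches give only these
  three totals; uniform annual increments within tranches are the natural
  realization for an annual-cycle model.
* Case fatality uses an exponential curve `f(t) = 1 − exp(−t/τ)`, as
  suggested by smoking-cessation evidence. No published time constant
  accompanies that evidence, so `τ` is exposed as configuration with a
  default of 5 years.
* Incidence responds immediately: the lag literature concerns mortality, and
  the incidence channel therefore sees the scenario concentration from the
  first post-intervention year.
* Lags delay benefits only: a concentration *increase* takes effect
  immediately.

## Scenarios and reporting

A scenario transforms each area's concentration once, instantaneously, at a
configurable year (default: at initialization) and holds it static:

* `cap` — concentrations above the cap (default 10 µg/m³, the WHO annual
  guideline) are capped; cleaner areas are untouched;
* `uniform_reduction` — a city-wide decrement (e.g. 3.6 µg/m³ for an
  emissions-directive compliance case), floored at the area's
  non-anthropogenic component, since a policy cannot remove natural
  background;
* `remove_anthropogenic` — concentration set to the non-anthropogenic
  component.

Scenario and base runs are differenced as ratios of totals:
`Δ = N_scenario/Pop_scenario − N_base/Pop_base`, scaled per
100,000, computed *after* aggregating to the requested stratification
(year, sex, age group, deprivation decile, area), not by averaging per-area
deltas. Reporting follows the working-age convention (ages 15–64, i.e. the
5-year bands from 15–19 through 60–64) and a 5-year running mean; the
running mean is centered with symmetric edge truncation, which preserves the
interior mean and commutes with affine transforms.

Both runs reuse the same per-area RNG stream (common random numbers): each
area's stream is seeded by a hash of the master seed and the area id, so
scenario deltas are driven by probability differences rather than sampling
noise, and an identical scenario yields deltas of exactly zero. An
independent-seed comparison is available simply by passing different master
seeds.

## Demography

Newborns are added at the end of each year by applying the area's general
fertility rate (GFR, live births per 1000 women aged 15–44) as an
independent Bernoulli trial per eligible woman, evaluated on ages at year
end. Newborns enter at age 0 in H1, male with probability 0.512 (the human
sex ratio at birth), and face no trials in their birth year. Migration is
zero, and baseline rates are held at their base-year values throughout —
both simplifying assumptions that weaken over long horizons. Survivors past
the top rate band keep top-band rates up to a hard maximum age of 110.

## Numerical and convention choices

* **Clamping, not crashing.** Adjusted probabilities above 1 are clamped,
  and negative non-disease mortality (possible when the case-fatality RR
  exceeds the all-cause RR at extreme exposure) is floored at 0. In the
  public calculus functions these emit warnings; inside the engine they are
  counted silently and reported in the run log, because a long run must not
  die on a legal-but-extreme stratum.
* **Banding.** Age bands are inclusive at both edges (0–4, 5–9, …), with the
  top band open-ended. Single-year expansion is piecewise constant; no
  interpolation scheme is assumed.
* **Incidence-year mortality.** The sequential-trial wording is only
  meaningful if the first trial's outcome selects the second trial's
  probability, so newly incident individuals face the diseased-state trial
  by default; `incident_year_mortality = "healthy"` switches to the
  alternative reading.
* **Tally conventions.** `n_population` is alive at year start (the delta
  denominator); events are counted during the year; `n_alive` and
  `n_prevalent` are measured at year end, banded by age at year start, so
  `n_alive = n_population − deaths` holds per stratum and
  `n_population(t+1) = n_alive(t) + n_births(t)` holds per area.
* **Cause attribution.** The diseased-state trial merges disease and
  other-cause hazards; a death from it is attributed to the disease by a
  conditional draw with probability `(P(M_IHD)/P(H2)) / P(M|H2)`, which
  preserves the expected disease-specific death count.

## The synthetic-data generator

No restricted census, burden-of-disease or dispersion-model extract ships
with the package; a generator produces schema-complete inputs with the
qualitative structure of the real sources. Choices, fixed once:

* **Age pyramid** — a mixture (22% children 0–17, 58% adults centred at
  age 30, 20% older adults centred at 62) reproducing the young-urban,
  peak-near-30 shape of a large-city population; totals are Poisson around
  1500 per area.
* **All-cause mortality** — Gompertz growth anchored to national life-table
  magnitudes: roughly 0.5–0.6% annual mortality in the late 50s rising to
  ~16% in the 95+ band. (An earlier internal calibration that overstated
  working-age mortality several-fold made the case-fatality survival effect
  implausibly dominant; the anchors above are what published life tables
  support.)
* **Disease mortality** — an age-increasing share (2% → ~15%, capped at
  25%) of all-cause mortality, so it can never exceed it.
* **Incidence and prevalence** — exponential age growth with
  non-decreasing band values; male rates exceed female rates by fixed
  ratios (1.4 incidence, 1.5 prevalence, ~1.2 mortality), consistent with
  men's higher underlying IHD burden.
* **Jitter** — band-to-band noise enters through positive growth factors
  and is shared between sexes, so every monotonicity and ordering
  constraint survives any seed.
* **Exposure** — total PM2.5 uniform over a configurable range (default
  8–16 µg/m³); the anthropogenic split is not described in the public
  sources, so the non-anthropogenic component is drawn independently in
  `[floor, total]` — the zero-anthropogenic scenario requires it to exist.
  The deprivation decile is uniform by default, with an optional
  rank-correlation knob linking pollution and deprivation for inequality
  experiments, since the real joint distribution is not published.

What the generator does **not** emulate: spatial autocorrelation of the
pollution field, the exact marginals of any real city, cohort effects, or
trends in baseline rates. Tests passing on synthetic data therefore
demonstrate the correctness of the calculus, engine and bookkeeping, and the
qualitative direction of scenario contrasts — not calibrated magnitudes for
any real population.

## Behaviour to expect from scenario contrasts

In the packaged experiments (100 areas × ~1500 people × 50 years, 20
replicate seeds, common random numbers, zero-anthropogenic scenario), the
working-age mortality benefit appears immediately at roughly the first
lag tranche and settles within two decades; the working-age prevalence
benefit builds as the large near-30 cohort ages into disease-prone years,
peaks mid-simulation, and then partially erodes — cleaner air also improves
survival *with* disease (case-fatality RR 1.21), which retains people in the
prevalent pool. That erosion is a real consequence of modelling morbidity
and mortality jointly, and it is why the packaged checks assert the
prevalence benefit over the mid-simulation window rather than at the
horizon. Male benefits exceed female benefits because male baseline disease
rates are higher.

## Problem sizes and runtime

The test suite runs the oracle-equivalence check on a single-stratum cohort
of 100,000 over 30 years × 20 seeds, and the scenario-contrast check on 100
areas × ~1500 people × 50 years × 20 seeds × 2 runs; together they complete
in a few minutes on one CPU. These sizes give Monte-Carlo standard errors
small enough for 3σ occupancy checks and clearly signed delta series; larger
populations shrink the noise further at proportional cost.

## Known limitations

Single disease, no co-morbidity; no sudden cardiac death from H1 (disease
death requires prior diagnosis); zero migration; static baseline rates;
static scenario concentrations; one exposure channel (PM2.5) with log-linear
response — no integrated exposure–response nonlinearity; deprivation
modelled as a static area attribute. Each is a deliberate scope boundary,
not an accident of implementation.
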