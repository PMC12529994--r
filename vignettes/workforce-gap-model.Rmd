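---
title: "Modelling hypertension care demand against workforce capacity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling hypertension care demand against workforce capacity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(htngap)
library(dplyr)
```

## The model and its assumptions

`htngap` treats hypertension care as a flow of clinic visits and asks, country
by country, whether the health workforce can deliver the flow the population
needs.

**Demand.** The number of people with hypertension in a country is the
prevalence estimate times an *eligible population* — the age band the
prevalence refers to. Annual visit demand multiplies that patient count by an
assumed visit schedule: 12 visits per patient per year (the high-demand base
case, reflecting monthly medication-refill visits common in low-income
settings), 6 (intermediate), 3 (low), or 1 (minimal). Demand uncertainty comes
entirely from the prevalence interval: the lower and upper bounds are the same
product with the interval limits in place of the point estimate. This is
exact-linear propagation — no distributional assumption is added on top of the
published intervals.

**Supply.** Provider densities are recorded per 10 000 *total* population, so
a country's provider head count is `density / 10 000 * population_total`. Each
provider is assumed to work 200 clinic days a year and see 20 patients a day
(base throughput) or 10 (low throughput), giving 4000 or 2000 annual visit
slots; 10% of provider time is assumed to go to hypertension care, leaving 400
or 200 hypertension slots per provider per year. The 10% fraction applies to
every cadre alike — an acknowledged simplification, and more likely an
over-estimate of physician time than of nurse time.

**Care models.** `physician_only` counts physicians; `nonphysician_only` sums
nurses, pharmacists, and community health workers (CHWs); `team` combines
both. A missing optional density contributes zero capacity rather than
excluding the country: CHW data exist for only about half of countries, and
dropping them would silently change every team-based aggregate. Team capacity
is therefore exactly the sum of the other two models, which the test suite
asserts as an identity.

**Gap.** `gap = demand − supply`, positive in deficit. Some published figures
use the opposite sign for display; reporting functions accept a
`sign = "surplus_positive"` switch, but the stored data keep one fixed
convention so that invariants (monotonicity, conservation) are unambiguous. A
country at exactly zero is *balanced* — surplus counting is strict
(`gap < 0`). The percentage gap is `100 * (demand − supply) / supply`; it
exceeds 100 when unmet need is more than double the capacity, and is
undefined (returned as `NA`, never a number) when supply is zero.

**Aggregation.** Cumulative gaps sum member countries within World Bank
income groups — point and both interval bounds independently — and the global
row is computed as the sum of the four group rows, so partition conservation
holds exactly rather than to rounding. Group-level prevalence and density
summaries are unweighted country means with sample standard deviations
(matching how the source statistics are quoted, which is inconsistent with
population weighting); a singleton group reports no SD.

## Parameters that matter

| Parameter | Units | Default | Rationale |
|---|---|---|---|
| `visits_per_year` | visits/patient/year | 12, 6, 3, 1 | monthly refills down to annual review |
| `patients_per_day` | patients/provider/day | 20 (base), 10 (low) | clinic throughput scenarios |
| `workdays_per_year` | days | 200 | standard working year net of leave |
| `hypertension_time_fraction` | proportion | 0.10 | share of provider time on hypertension |
| `adult_fraction` | proportion | 0.6 | see below |
| income thresholds | US$ GNI/capita | 1085 / 4255 / 13845 | World Bank 2023 classification |

**The eligible population.** Prevalence estimates for hypertension cover ages
30 and over, while densities and populations are whole-country. The published
headline counts (1.8 billion patients among 8.0 billion people at ≈37.5%
prevalence) imply the prevalence was applied to roughly 60% of the total
population. The data model therefore carries an explicit
`population_eligible` field; when assembling real data without an adult-count
column, it defaults to `population_total × adult_fraction` with
`adult_fraction = 0.6`. This keeps the age-band ambiguity in one named,
configurable place.

**Income-group boundaries.** Published threshold ranges quote the same dollar
figure at the top of one band and the bottom of the next. `classify_income()`
resolves this as upper-inclusive half-open intervals (≤1085, ≤4255, ≤13845,
above), a total monotone step function — every GNI value maps to exactly one
group, and raising GNI never lowers the group.

## What the synthetic generator emulates — and what it does not

`generate_dataset()` reproduces the *marginal, group-conditional* structure
of the real inputs:

- 199 countries split 61/64/49/25 across HIC/UMIC/LMIC/LIC;
- provider densities drawn from normals truncated at zero with the observed
  group means (physicians 1.9/7.8/20.7/33.8 per 10 000 from LIC to HIC,
  nurses 14.8/20.8/40.8/88.7, pharmacists 0.6/1.7/3.1/8.0). Per-group spreads
  are not published, so each cadre's pooled coefficient of variation
  (e.g. nurses 54.1/47.3 ≈ 1.14) is applied to its group mean; because the
  nurse CV exceeds 1, truncation is genuinely active, which is why a
  truncated family is mandatory;
- CHW density from the pooled figure (mean 3.4, SD 7.3, capped at the
  observed maximum 44.9 per 10 000) and set missing with probability
  `1 − 96/199`, reproducing the half-missing CHW coverage;
- prevalence from a normal on the percent scale with the observed group
  means and SDs (36.7 (4.8) / 36.1 (5.7) / 40.3 (6.7) / 36.2 (7.0) from LIC
  to HIC), clipped to (5, 80); interval half-width fixed at 6 percentage
  points (interval widths are not published; 6 points is typical of
  country-level prevalence intervals) and configurable;
- total population log-uniform between 10⁴ and 1.4 × 10⁹, mimicking the
  heavy-tailed country-size distribution.

It deliberately does **not** reproduce inter-indicator correlations: in real
data, population size, GNI, and densities are correlated (large poor
countries drive global totals), whereas the generator draws them
independently given the income group. Passing tests on synthetic data
therefore validate the *arithmetic and its invariants* — monotonicity,
additivity, conservation, interval ordering, determinism — not the real
world's magnitudes. Global totals from synthetic runs are scaled differently
from published ones (a log-uniform population mix has no India or China), and
qualitative patterns (universal physician-only deficits under monthly visits;
team-based care easing every country's gap) are checked instead.

Truncation shifts the realised mean of a zero-truncated normal above the
configured location parameter. The generator does not correct for this — the
configured values parameterise the *pre-truncation* normal — and the
parameter-recovery test compares sample means against a truncation-corrected
reference computed by an independent Monte-Carlo rejection sampler, within
three standard errors at 500 countries per group.

## Numerical choices

- **Truncated-normal sampling** uses the inverse-CDF transform (a uniform
  mapped through `qnorm` restricted to the mass above zero). It is exact, and
  consumes exactly one uniform per draw, so a dataset is a pure function of
  its seed regardless of parameter values — a rejection loop would make the
  draw count, and hence the whole stream, parameter-dependent.
- **Determinism**: the generator seeds R's RNG itself; pipeline outputs are
  byte-identical across identical invocations, and the output manifest
  records input checksums, all parameters, and the package version (never a
  timestamp).
- **Tie-breaks**: extreme-country ranking breaks ties by iso3 lexicographic
  order (candidates are pre-sorted by code, and the first maximum wins).
- **Degenerate inputs**: a zero-width prevalence interval collapses the gap
  interval to a point; zero prevalence yields zero demand and puts every
  country with any provider in surplus; zero supply makes the percentage gap
  `NA`; a zero-density cadre contributes exactly zero capacity.
- **No rounding** anywhere in stored results; millions-scale, one-decimal
  formatting happens only in reports and plots.
- **Exact conservation**: the global aggregate is defined as the sum of the
  group aggregates, making the partition identity hold bitwise instead of to
  floating-point rearrangement error.

## Problem sizes used in the tests

The suite exercises the full 199-country, 24-cell grid for end-to-end and
determinism checks; 100 randomly-composed datasets of at most 12 countries
for the brute-force scalar oracle comparison (which matches the pipeline
bit-for-bit, including aggregates, surplus counts, and extremes); five
24-country datasets for the property suite; and 500 countries per income
group (2000 total) with 2 × 10⁵ Monte-Carlo draws per parameter set for
parameter recovery. These sizes give the properties room to fail while
keeping the suite quick to run.

## Known limitations

- Country-level aggregation hides within-country variation (urban/rural
  density differences); the model says nothing about distribution.
- The 10% time fraction, the 200-day year, and uniform throughput across
  cadres are assumptions, not estimates; results scale linearly in each, so
  readers can re-scale mentally.
- Demand covers *all* prevalent cases, not only diagnosed or treated
  patients — deliberately, since the aim is the capacity needed for full
  coverage — so gaps overstate the shortfall relative to current
  care-seeking.
- Supply carries no uncertainty; density data are treated as exact, and the
  reported intervals reflect prevalence uncertainty only.
- No temporal dimension: a single cross-section, no workforce growth or
  migration dynamics.
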