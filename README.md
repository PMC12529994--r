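# htngap

Country-level modelling of the gap between the clinic visits people with
hypertension need and the visits a country's health workforce can deliver.

Hypertension control depends on regular follow-up — in many low- and
middle-income settings, a monthly clinic visit for medication refills. Whether
a health system can deliver that schedule depends on how many physicians,
nurses, pharmacists, and community health workers (CHWs) it has, and on which
of those cadres share the work. `htngap` is for health-systems and
epidemiology researchers who want to quantify that supply–demand balance per
country, per income group, and globally, under explicit scenario assumptions,
with uncertainty carried through from the prevalence estimates.

## The model

For a country with eligible population $N$, hypertension prevalence $p$ (with
95% CI $[p_{lo}, p_{hi}]$), and provider density $\rho_k$ (cadre $k$, per
10 000 total population $N_{tot}$):

- **Demand** (visits/year): $D = v \cdot p \cdot N$, where $v \in \{12, 6, 3,
  1\}$ is the assumed visits per patient per year (high/base, intermediate,
  low, minimal). Interval bounds replace $p$ by $p_{lo}$ and $p_{hi}$.
- **Supply** (visits/year): $S = \frac{\rho}{10\,000} \cdot N_{tot} \cdot c
  \cdot w \cdot f$, with throughput $c \in \{20, 10\}$ patients/day, $w = 200$
  workdays/year, and $f = 0.10$ the fraction of provider time spent on
  hypertension care. With base parameters each provider contributes
  $20 \times 200 = 4000$ annual visit slots, 400 of them for hypertension.
- **Care models**: $\rho$ is the physician density (`physician_only`), the
  sum of nurse + pharmacist + CHW densities (`nonphysician_only`, missing
  densities contributing zero), or their total (`team`), so team capacity is
  exactly the sum of the other two.
- **Gap**: $G = D - S$; positive is a deficit, negative a surplus. Gaps are
  summed within World Bank income groups (LIC/LMIC/UMIC/HIC, GNI/capita
  thresholds 1085/4255/13845 US$) and globally, point and CI bounds
  independently; the percentage gap is $100\,(D - S)/S$.

The full scenario grid is 4 visit schedules × 2 throughput levels × 3 care
models = 24 cells. A synthetic-data generator reproduces the structure of the
real inputs (199 countries split 61/64/49/25 across HIC/UMIC/LMIC/LIC,
income-group-conditional densities and prevalence, CHW data present for only
about 96 countries), so the whole pipeline runs and is tested without any
download. Readers for World Bank indicator layouts (long and wide),
NCD-RisC-style prevalence tables, and an assembly step with the
physician-density inclusion rule are included for working with the real data.

## Worked example

```r
library(htngap)

d <- generate_dataset(generator_config(seed = 42))
fit <- gap_analysis(d)
fit
#> <htn_gap_analysis>
#>   countries: 199 (CHW data for 91)
#>   scenarios: 24 cells
#>   global cumulative gap (millions of visits/year):
#>     v12_c10_nonphysician_only       33098.0 [22490.6, 43705.3]
#>     v12_c10_physician_only          53390.6 [42783.2, 63998.0]
#>     v12_c10_team                    23168.7 [12561.3, 33776.1]
#>     v12_c20_nonphysician_only        2876.1 [-7731.3, 13483.5]
#>     v12_c20_physician_only          43461.3 [32853.9, 54068.7]
#>     v12_c20_team                   -16982.4 [-27589.8, -6375.0]
#>     ... and 18 more cells
```

Under the high-demand physician-only scenario (12 visits/patient/year, 20
patients/provider/day) this synthetic world needs about 43.5 billion more
visits per year than its physicians can supply (CI from the prevalence
intervals); team-based care flips the global balance to a surplus of about
17.0 billion visit slots. Per-country results are a tidy tibble:

```r
g <- tidy(fit) |> dplyr::filter(scenario == "v12_c20_physician_only")
count_surplus_countries(g)
#> [1] 16
rank_extremes(g)$largest_deficit
#> # A tibble: 1 × 2
#>   iso3          gap
#>   <chr>       <dbl>
#> 1 AAW   3285887388.
```

So 16 of 199 synthetic countries have physician capacity exceeding even the
monthly-visit demand, and the largest single-country deficit is ≈3.3 billion
visits/year. `summarize_gaps()`/`fit$summary` give the income-group and
global aggregates, `autoplot(fit)` draws them, and `run_pipeline()` writes
per-country and summary CSV/JSON artifacts plus a checksummed manifest;
`summarize_run()` turns an output directory into a plain-text report. A thin
CLI wrapping these functions ships in `inst/cli/htngap` (subcommands
`generate`, `run`, `report`).

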