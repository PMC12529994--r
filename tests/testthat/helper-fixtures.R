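# Shared fixtures and independent scalar oracles.
#
# The oracles deliberately avoid the package's vectorised code paths: plain
# for-loops and scalar arithmetic, written straight from the model
# definition, so agreement with the pipeline is a genuine cross-check.

# A small hand-built dataset; every number chosen for easy mental arithmetic.
toy_dataset <- function() {
  tibble::tibble(
    iso3 = c("AAA", "BBB", "CCC"),
    name = c("Alpha", "Beta", "Gamma"),
    population_total = c(1e6, 1e7, 5e5),
    population_eligible = c(6e5, 6e6, 3e5),
    income_group = factor(c("LIC", "UMIC", "HIC"),
                          levels = c("LIC", "LMIC", "UMIC", "HIC")),
    density_physician = c(2, 10, 40),
    density_nurse = c(15, 30, NA),
    density_pharmacist = c(1, 3, 9),
    density_chw = c(NA, 5, 0),
    prevalence = c(0.375, 0.40, 0.30),
    prevalence_lo = c(0.309, 0.35, 0.25),
    prevalence_hi = c(0.441, 0.45, 0.35)
  )
}

# A generator config with few countries, for fast randomised cases.
small_config <- function(seed, counts = c(HIC = 2, UMIC = 3, LMIC = 3, LIC = 2)) {
  generator_config(n_countries_by_group = counts, seed = seed)
}

# Scalar recomputation of one country-scenario cell.
oracle_cell <- function(row, visits, ppd, model,
                        workdays = 200, fraction = 0.10) {
  # patients first, then the visit schedule (the model's own reading:
  # "patients with hypertension times visits per year")
  patients <- row$prevalence * row$population_eligible
  patients_lo <- row$prevalence_lo * row$population_eligible
  patients_hi <- row$prevalence_hi * row$population_eligible
  demand <- visits * patients
  demand_lo <- visits * patients_lo
  demand_hi <- visits * patients_hi
  na0 <- function(x) if (is.na(x)) 0 else x
  nonphys <- na0(row$density_nurse) + na0(row$density_pharmacist) +
    na0(row$density_chw)
  density <- switch(model,
    physician_only = row$density_physician,
    nonphysician_only = nonphys,
    team = row$density_physician + nonphys
  )
  supply <- (density / 1e4) * row$population_total * ppd * workdays * fraction
  list(
    demand = demand, demand_lo = demand_lo, demand_hi = demand_hi,
    supply = supply,
    gap = demand - supply, gap_lo = demand_lo - supply, gap_hi = demand_hi - supply,
    gap_pct = if (supply == 0) NA_real_ else 100 * (demand - supply) / supply,
    is_surplus = (demand - supply) < 0
  )
}

# Full 24-cell grid by explicit loops, mirroring compute_gaps() row order
# (scenario-major, countries in dataset order).
oracle_grid <- function(data, visits_set = c(12, 6, 3, 1), ppd_set = c(20, 10),
                        models = c("physician_only", "nonphysician_only", "team")) {
  n <- nrow(data)
  total <- length(visits_set) * length(ppd_set) * length(models) * n
  out <- data.frame(
    iso3 = character(total), scenario = character(total),
    visits_per_year = numeric(total), patients_per_day = numeric(total),
    care_model = character(total),
    demand = numeric(total), demand_lo = numeric(total), demand_hi = numeric(total),
    supply = numeric(total), gap = numeric(total), gap_lo = numeric(total),
    gap_hi = numeric(total), gap_pct = numeric(total), is_surplus = logical(total)
  )
  k <- 0L
  for (v in visits_set) {
    for (p in ppd_set) {
      for (m in models) {
        lab <- paste0("v", v, "_c", p, "_", m)
        for (i in seq_len(n)) {
          cell <- oracle_cell(data[i, ], v, p, m)
          k <- k + 1L
          out$iso3[k] <- data$iso3[i]
          out$scenario[k] <- lab
          out$visits_per_year[k] <- v
          out$patients_per_day[k] <- p
          out$care_model[k] <- m
          for (fld in c("demand", "demand_lo", "demand_hi", "supply", "gap",
                        "gap_lo", "gap_hi", "gap_pct", "is_surplus")) {
            out[[fld]][k] <- cell[[fld]]
          }
        }
      }
    }
  }
  out
}

# Scalar aggregation mirroring summarize_gaps(): per-group sums in income
# level order, and the global total as the sum of group totals.
oracle_global_sum <- function(values, income_group) {
  group_totals <- numeric(0)
  for (grp in levels(income_group)) {
    member <- values[income_group == grp]
    if (length(member) > 0) group_totals <- c(group_totals, sum(member))
  }
  sum(group_totals)
}

# Monte-Carlo oracle for the mean of a normal truncated at zero (optionally
# upper-capped), by rejection sampling — an independent route from the
# generator's inverse-CDF draw. Returns the mean and its MC standard error.
mc_truncnorm_mean <- function(m, s, cap = Inf, n = 2e5) {
  draws <- rnorm(3 * n, m, s)
  draws <- draws[draws > 0]
  while (length(draws) < n) {
    extra <- rnorm(n, m, s)
    draws <- c(draws, extra[extra > 0])
  }
  draws <- pmin(draws[seq_len(n)], cap)
  c(mean = mean(draws), se = stats::sd(draws) / sqrt(n))
}

# Same, for prevalence: normal on the percent scale clipped to (5, 80).
mc_clipped_prevalence_mean <- function(m, s, n = 2e5) {
  draws <- pmin(pmax(rnorm(n, m, s), 5), 80)
  c(mean = mean(draws), se = stats::sd(draws) / sqrt(n))
}
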