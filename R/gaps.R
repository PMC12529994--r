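# Per-country gap computation with interval propagation, and the
# aggregations the results are reported with.
#
# Sign convention: gap = demand - supply, so positive means deficit and
# negative means surplus. Supply carries no uncertainty; the interval on
# the gap comes entirely from the prevalence interval, propagated linearly
# through demand.

#' Percentage gap between demand and capacity
#'
#' `100 * (demand - supply) / supply`: 0 when the system is exactly
#' balanced, 100 when demand is double the supply (values above 100 mean
#' unmet need exceeds the available capacity more than twofold), negative
#' in surplus. Undefined when supply is zero; returned as `NA` rather than
#' a number.
#'
#' @param demand,supply visits per year (vectorised)
#' @return percentage, same length as the inputs
#' @examples
#' gap_percentage(c(400, 800, 200), c(400, 400, 400))
#' @export
gap_percentage <- function(demand, supply) {
  out <- 100 * (demand - supply) / supply
  out[supply == 0] <- NA_real_
  out
}

#' Compute per-country gaps over a scenario grid
#'
#' For every country and every scenario cell: demand from the visit
#' schedule, supply from the care model at the scenario's throughput, and
#' the gap with interval bounds (`gap = demand - supply`; bounds subtract
#' the same supply from the demand bounds, so `gap_lo <= gap <= gap_hi`
#' always holds).
#'
#' @param data a country dataset tibble
#' @param scenarios a [scenario_grid()] tibble (defaults to the full
#'   24-cell grid)
#' @param params a [capacity_params()] object; its `patients_per_day` is
#'   overridden cell by cell by the scenario's throughput
#'
#' @return tibble with one row per country-scenario: iso3, income group,
#'   the scenario descriptors, `demand`/`demand_lo`/`demand_hi`, `supply`,
#'   `gap`/`gap_lo`/`gap_hi`, `gap_pct` and `is_surplus` (`gap < 0`)
#' @examples
#' d <- generate_dataset(generator_config(seed = 1))
#' g <- compute_gaps(d, scenario_grid(visits_per_year = 12, care_model = "team"))
#' dplyr::count(g, is_surplus)
#' @export
compute_gaps <- function(data, scenarios = scenario_grid(), params = capacity_params()) {
  data <- validate_dataset(data)
  stopifnot(inherits(params, "capacity_params"))
  if (nrow(scenarios) == 0) {
    abort("scenario grid is empty", class = "htngap_validation_error")
  }

  base <- patients_with_hypertension(data)

  purrr::pmap(
    scenarios[c("scenario", "visits_per_year", "patients_per_day", "care_model")],
    function(scenario, visits_per_year, patients_per_day, care_model) {
      cell_params <- capacity_params(
        workdays_per_year = params$workdays_per_year,
        patients_per_day = patients_per_day,
        hypertension_time_fraction = params$hypertension_time_fraction
      )
      supply <- care_model_capacity(base, as.character(care_model), cell_params)
      base |>
        annual_demand(visits_per_year) |>
        dplyr::mutate(
          scenario = scenario,
          visits_per_year = visits_per_year,
          patients_per_day = patients_per_day,
          care_model = factor(as.character(care_model), levels = care_model_levels()),
          supply = supply
        )
    }
  ) |>
    dplyr::bind_rows() |>
    dplyr::mutate(
      gap = .data$demand - .data$supply,
      gap_lo = .data$demand_lo - .data$supply,
      gap_hi = .data$demand_hi - .data$supply,
      gap_pct = gap_percentage(.data$demand, .data$supply),
      is_surplus = .data$gap < 0
    ) |>
    dplyr::select(
      "iso3", "income_group", "scenario", "visits_per_year",
      "patients_per_day", "care_model", "demand", "demand_lo", "demand_hi",
      "supply", "gap", "gap_lo", "gap_hi", "gap_pct", "is_surplus"
    )
}

#' Aggregate gaps by income group and globally
#'
#' For each scenario cell, sums member-country gaps (point and both
#' interval bounds independently) within each income group and over all
#' countries (`GLOBAL`), counts surplus countries, and reports unweighted
#' country-level means with sample SDs of prevalence (percent) and of each
#' provider density. The global row of each scenario equals the sum of its
#' four group rows exactly.
#'
#' @param gaps output of [compute_gaps()]
#' @param data the country dataset the gaps were computed from
#' @return tibble with one row per scenario x (income group or GLOBAL)
#' @export
summarize_gaps <- function(gaps, data) {
  data <- validate_dataset(data)
  if (!all(gaps$iso3 %in% data$iso3)) {
    abort("gap results reference countries absent from the dataset",
          class = "htngap_consistency_error")
  }

  mean_or_na <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  sd_or_na <- function(x) if (sum(!is.na(x)) < 2) NA_real_ else sd(x, na.rm = TRUE)

  summarise_block <- function(g, d) {
    dplyr::summarise(
      g,
      n_countries = dplyr::n(),
      n_surplus = sum(.data$is_surplus),
      cumulative_gap = sum(.data$gap),
      cumulative_gap_lo = sum(.data$gap_lo),
      cumulative_gap_hi = sum(.data$gap_hi),
      cumulative_demand = sum(.data$demand),
      cumulative_supply = sum(.data$supply),
      .groups = "drop"
    ) |>
      dplyr::left_join(d, by = "income_group")
  }

  descr <- function(d) {
    dplyr::summarise(
      d,
      mean_prevalence = 100 * mean(.data$prevalence),
      sd_prevalence = 100 * sd_or_na(.data$prevalence),
      mean_density_physician = mean(.data$density_physician),
      sd_density_physician = sd_or_na(.data$density_physician),
      mean_density_nurse = mean_or_na(.data$density_nurse),
      sd_density_nurse = sd_or_na(.data$density_nurse),
      mean_density_pharmacist = mean_or_na(.data$density_pharmacist),
      sd_density_pharmacist = sd_or_na(.data$density_pharmacist),
      mean_density_chw = mean_or_na(.data$density_chw),
      sd_density_chw = sd_or_na(.data$density_chw),
      .groups = "drop"
    )
  }

  by_group <- gaps |>
    dplyr::group_by(.data$income_group, .data$scenario, .data$visits_per_year,
                    .data$patients_per_day, .data$care_model) |>
    summarise_block(descr(dplyr::group_by(data, .data$income_group)))

  # the global row is the sum of its group rows, so partition conservation
  # holds exactly, not merely to rounding
  global <- by_group |>
    dplyr::group_by(.data$scenario, .data$visits_per_year,
                    .data$patients_per_day, .data$care_model) |>
    dplyr::summarise(
      income_group = "GLOBAL",
      dplyr::across(c("n_countries", "n_surplus", "cumulative_gap",
                      "cumulative_gap_lo", "cumulative_gap_hi",
                      "cumulative_demand", "cumulative_supply"), sum),
      .groups = "drop"
    ) |>
    dplyr::left_join(dplyr::mutate(descr(data), income_group = "GLOBAL"),
                     by = "income_group")

  dplyr::bind_rows(
    dplyr::mutate(by_group, income_group = as.character(.data$income_group)),
    global
  ) |>
    dplyr::mutate(income_group = factor(.data$income_group,
                                        levels = c(income_levels(), "GLOBAL"))) |>
    dplyr::arrange(.data$scenario, .data$income_group)
}

# One scenario cell, one row per country — shared precondition of the
# surplus count and the extremes ranking.
check_one_per_country <- function(gaps) {
  if (nrow(gaps) == 0) {
    abort("no gap results supplied", class = "htngap_validation_error")
  }
  if (length(unique(gaps$scenario)) > 1) {
    abort("gap results span more than one scenario; filter to one cell first",
          class = "htngap_consistency_error")
  }
  if (anyDuplicated(gaps$iso3)) {
    abort(paste0("duplicate country in gap results: ",
                 gaps$iso3[duplicated(gaps$iso3)][1]),
          class = "htngap_consistency_error")
  }
  invisible(gaps)
}

#' Count countries in surplus
#'
#' Number of countries whose capacity strictly exceeds demand (`gap < 0`)
#' in one scenario cell. A country at exactly zero gap is balanced, neither
#' deficit nor surplus.
#'
#' @param gaps [compute_gaps()] rows for a single scenario cell, one per
#'   country
#' @return integer count
#' @export
count_surplus_countries <- function(gaps) {
  check_one_per_country(gaps)
  sum(gaps$gap < 0)
}

#' Extreme countries in one scenario cell
#'
#' The largest deficit (most positive gap) and the largest surplus (most
#' negative gap) across countries; ties broken by iso3 lexicographic order.
#' Either extreme is absent (`NULL`) when no country is on that side of
#' zero.
#'
#' @inheritParams count_surplus_countries
#' @return list with elements `largest_deficit` and `largest_surplus`,
#'   each a one-row tibble (`iso3`, `gap`) or `NULL`
#' @export
rank_extremes <- function(gaps) {
  check_one_per_country(gaps)
  ordered <- gaps |>
    dplyr::select("iso3", "gap") |>
    dplyr::arrange(.data$iso3)
  deficit <- ordered |> dplyr::filter(.data$gap > 0)
  surplus <- ordered |> dplyr::filter(.data$gap < 0)
  list(
    largest_deficit = if (nrow(deficit) > 0) {
      deficit[which.max(deficit$gap), ] # which.max keeps the first (iso3-sorted) tie
    },
    largest_surplus = if (nrow(surplus) > 0) {
      surplus[which.min(surplus$gap), ]
    }
  )
}
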