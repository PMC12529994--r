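# Core arithmetic of the supply-demand model.
#
# Demand: visits/year = visits_per_year x prevalence x eligible population.
# Supply: visits/year = (density / 10 000) x total population
#                       x patients_per_day x workdays_per_year
#                       x hypertension_time_fraction.
# With base parameters one provider contributes 20 x 200 = 4000 visit slots
# a year, of which 10% — 400 — go to hypertension care.

#' Provider capacity parameters
#'
#' @param workdays_per_year clinic days a provider works per year (default 200)
#' @param patients_per_day patients a provider sees per clinic day: 20 under
#'   base throughput, 10 under the low-capacity scenario
#' @param hypertension_time_fraction share of provider time spent on
#'   hypertension services (default 0.10), applied identically to every cadre
#'
#' @return a list of class `capacity_params`
#' @examples
#' capacity_params()
#' capacity_params(patients_per_day = 10)
#' @export
capacity_params <- function(workdays_per_year = 200,
                            patients_per_day = 20,
                            hypertension_time_fraction = 0.10) {
  if (workdays_per_year <= 0 || patients_per_day <= 0 ||
      hypertension_time_fraction <= 0 || hypertension_time_fraction > 1) {
    abort(paste0("capacity parameters must satisfy workdays > 0, ",
                 "patients/day > 0, 0 < time fraction <= 1"),
          class = "htngap_validation_error")
  }
  structure(
    list(
      workdays_per_year = workdays_per_year,
      patients_per_day = patients_per_day,
      hypertension_time_fraction = hypertension_time_fraction
    ),
    class = "capacity_params"
  )
}

#' The scenario grid
#'
#' Full factorial grid of visit-frequency, throughput, and care-model
#' assumptions: 4 visit schedules x 2 throughput levels x 3 care models =
#' 24 cells by default. Each cell carries a diff-friendly label such as
#' `v12_c20_team`.
#'
#' @param visits_per_year annual clinic visits assumed per patient; defaults
#'   to 12 (high demand / base), 6 (intermediate), 3 (low), 1 (minimal)
#' @param patients_per_day provider throughput levels; defaults to 20 (base)
#'   and 10 (low capacity)
#' @param care_model which cadres deliver the visits: `physician_only`,
#'   `nonphysician_only` (nurses + pharmacists + community health workers),
#'   or `team` (all combined)
#'
#' @return tibble with columns `scenario`, `visits_per_year`,
#'   `patients_per_day`, `care_model`
#' @examples
#' scenario_grid()
#' scenario_grid(visits_per_year = 12, care_model = "team")
#' @export
scenario_grid <- function(visits_per_year = c(12, 6, 3, 1),
                          patients_per_day = c(20, 10),
                          care_model = care_model_levels()) {
  if (any(visits_per_year <= 0)) {
    abort("visits_per_year must be positive", class = "htngap_validation_error")
  }
  if (any(patients_per_day <= 0)) {
    abort("patients_per_day must be positive", class = "htngap_validation_error")
  }
  if (!all(care_model %in% care_model_levels())) {
    abort(paste0("unknown care model: ",
                 paste(setdiff(care_model, care_model_levels()), collapse = ", ")),
          class = "htngap_validation_error")
  }
  tidyr::expand_grid(
    visits_per_year = visits_per_year,
    patients_per_day = patients_per_day,
    care_model = factor(care_model, levels = care_model_levels())
  ) |>
    dplyr::mutate(
      scenario = paste0("v", .data$visits_per_year, "_c", .data$patients_per_day,
                        "_", .data$care_model),
      .before = 1
    )
}

#' Patients with hypertension per country
#'
#' Point estimate and interval bounds for the number of people with
#' hypertension: prevalence (and its 95% interval limits) times the
#' eligible population.
#'
#' @param data a country dataset tibble
#' @return the input with columns `patients`, `patients_lo`, `patients_hi`
#'   appended
#' @examples
#' generate_dataset(generator_config(seed = 1)) |>
#'   patients_with_hypertension() |>
#'   dplyr::select(iso3, patients, patients_lo, patients_hi)
#' @export
patients_with_hypertension <- function(data) {
  data |>
    dplyr::mutate(
      patients = .data$prevalence * .data$population_eligible,
      patients_lo = .data$prevalence_lo * .data$population_eligible,
      patients_hi = .data$prevalence_hi * .data$population_eligible
    )
}

#' Annual visit demand
#'
#' Multiplies patient counts by the assumed number of clinic visits per
#' patient per year; linear in both arguments, interval bounds scale with
#' the point estimate.
#'
#' @param data tibble with `patients`, `patients_lo`, `patients_hi` columns
#'   (see [patients_with_hypertension()])
#' @param visits_per_year assumed annual visits per patient; must be > 0
#' @return the input with `demand`, `demand_lo`, `demand_hi` (visits/year)
#'   appended
#' @export
annual_demand <- function(data, visits_per_year) {
  if (length(visits_per_year) != 1 || visits_per_year <= 0) {
    abort("visits_per_year must be a single positive number",
          class = "htngap_validation_error")
  }
  data |>
    dplyr::mutate(
      demand = visits_per_year * .data$patients,
      demand_lo = visits_per_year * .data$patients_lo,
      demand_hi = visits_per_year * .data$patients_hi
    )
}

#' Annual visit capacity of one provider cadre
#'
#' Converts a provider density into deliverable hypertension visits per
#' year: `(density / 10 000) * population * patients_per_day *
#' workdays_per_year * hypertension_time_fraction`. Densities are per
#' 10 000 total population, so the provider head count uses the total
#' population, not the eligible population.
#'
#' @param density providers per 10 000 total population (vectorised)
#' @param population_total total population (vectorised)
#' @param params a [capacity_params()] object
#' @return hypertension visits per year, same length as the inputs
#' @examples
#' provider_capacity(10, 1e6) # 1000 providers x 400 slots = 400 000
#' @export
provider_capacity <- function(density, population_total, params = capacity_params()) {
  stopifnot(inherits(params, "capacity_params"))
  if (any(density < 0, na.rm = TRUE)) {
    abort("density must be non-negative", class = "htngap_validation_error")
  }
  (density / 1e4) * population_total *
    params$patients_per_day * params$workdays_per_year *
    params$hypertension_time_fraction
}

#' Visit capacity under a care model
#'
#' `physician_only` counts physician density alone; `nonphysician_only`
#' sums nurse, pharmacist and community-health-worker densities, treating a
#' missing density as zero capacity (so countries without CHW data stay in
#' the analysis); `team` combines both, and is exactly the sum of the other
#' two models.
#'
#' @param data a country dataset tibble
#' @param care_model one of `"physician_only"`, `"nonphysician_only"`, `"team"`
#' @param params a [capacity_params()] object
#' @return numeric vector of hypertension visits per year, one per row
#' @examples
#' d <- generate_dataset(generator_config(seed = 1))
#' all.equal(
#'   care_model_capacity(d, "team"),
#'   care_model_capacity(d, "physician_only") +
#'     care_model_capacity(d, "nonphysician_only")
#' )
#' @export
care_model_capacity <- function(data, care_model, params = capacity_params()) {
  if (length(care_model) != 1 || !care_model %in% care_model_levels()) {
    abort(paste0("unknown care model: ", paste(care_model, collapse = ", ")),
          class = "htngap_validation_error")
  }
  nonphys <- dplyr::coalesce(data$density_nurse, 0) +
    dplyr::coalesce(data$density_pharmacist, 0) +
    dplyr::coalesce(data$density_chw, 0)
  density <- switch(as.character(care_model),
    physician_only = data$density_physician,
    nonphysician_only = nonphys,
    team = data$density_physician + nonphys
  )
  provider_capacity(density, data$population_total, params)
}
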