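# Country dataset: validation, assembly with the physician-density
# inclusion rule, and small accessors.

#' Validate a country dataset
#'
#' Checks the invariants every downstream computation relies on:
#' unique iso3 codes; positive populations with
#' `population_eligible <= population_total`; a non-missing, non-negative
#' physician density for every row (the inclusion rule); non-negative
#' optional densities where present; prevalence with
#' `0 <= lower <= point <= upper <= 1`; and a recognised income group.
#'
#' @param data tibble with the canonical dataset columns (see
#'   [write_dataset()] for the list)
#' @return the validated tibble, with `income_group` as an ordered-level
#'   factor and columns in canonical order
#' @examples
#' validate_dataset(generate_dataset(generator_config(seed = 1)))
#' @export
validate_dataset <- function(data) {
  data <- as_tibble(data)
  missing_cols <- setdiff(dataset_columns(), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("dataset lacks columns: ", paste(missing_cols, collapse = ", ")),
          class = "htngap_validation_error")
  }
  data <- dplyr::select(data, dplyr::all_of(dataset_columns()))
  if (nrow(data) == 0) {
    abort("dataset has zero rows", class = "htngap_validation_error")
  }
  if (anyDuplicated(data$iso3)) {
    dup <- data$iso3[duplicated(data$iso3)][1]
    abort(paste0("duplicate iso3 code: ", dup), class = "htngap_validation_error")
  }
  if (!is.factor(data$income_group)) {
    data$income_group <- factor(data$income_group, levels = income_levels())
  }
  fail <- function(cond, msg) {
    bad <- which(cond)
    if (length(bad) > 0) {
      abort(paste0(msg, " (first offender: ", data$iso3[bad[1]], ")"),
            class = "htngap_validation_error")
    }
  }
  fail(is.na(data$income_group), "unrecognised income group")
  fail(!is.finite(data$population_total) | data$population_total <= 0,
       "population_total must be positive")
  fail(!is.finite(data$population_eligible) | data$population_eligible <= 0,
       "population_eligible must be positive")
  fail(data$population_eligible > data$population_total,
       "population_eligible exceeds population_total")
  fail(is.na(data$density_physician) | data$density_physician < 0,
       "physician density must be present and non-negative")
  for (col in c("density_nurse", "density_pharmacist", "density_chw")) {
    fail(!is.na(data[[col]]) & data[[col]] < 0,
         paste0(col, " must be non-negative when present"))
  }
  fail(is.na(data$prevalence) | is.na(data$prevalence_lo) | is.na(data$prevalence_hi),
       "prevalence and its interval bounds must be present")
  fail(data$prevalence_lo < 0 | data$prevalence_hi > 1 |
         data$prevalence_lo > data$prevalence | data$prevalence > data$prevalence_hi,
       "prevalence interval must satisfy 0 <= lower <= point <= upper <= 1")
  data
}

#' Count countries with community-health-worker data
#'
#' @param data a country dataset tibble
#' @return integer count of rows with non-missing `density_chw`
#' @export
chw_coverage <- function(data) {
  sum(!is.na(data$density_chw))
}

#' Assemble a country dataset from source tables
#'
#' Joins per-provider density tables, prevalence, population and income
#' information on iso3 code and applies the inclusion rule: a country enters
#' the dataset only if it has a physician density, a prevalence estimate, a
#' population count and an income classification. Countries failing any of
#' those are dropped with a logged reason. Optional densities (nurse,
#' pharmacist, community health worker) are attached where available and
#' left missing otherwise.
#'
#' @param densities named list of tibbles as returned by
#'   [read_density_table()]; recognised names are `physician`, `nurse`,
#'   `pharmacist`, `chw`; `physician` is required
#' @param prevalence tibble as returned by [read_prevalence_table()]
#' @param population tibble with columns `iso3`, `population_total` and
#'   optionally `name` and `population_eligible`; when the eligible count is
#'   absent it defaults to `population_total * adult_fraction`
#' @param income tibble with `iso3` and either an `income_group` column or a
#'   `gni_per_capita` column to be classified via [classify_income()]
#' @param adult_fraction share of the total population in the age band the
#'   prevalence estimates refer to; used only when `population` carries no
#'   explicit `population_eligible` column. Default 0.6.
#' @param thresholds an [income_thresholds()] object, used when `income`
#'   carries GNI rather than pre-assigned groups
#' @param quiet suppress the per-country drop log
#'
#' @return a validated country dataset tibble (one row per surviving country)
#' @export
assemble_dataset <- function(densities, prevalence, population, income,
                             adult_fraction = 0.6,
                             thresholds = income_thresholds(),
                             quiet = FALSE) {
  if (!is.list(densities) || is.null(densities$physician)) {
    abort("densities must be a named list containing at least $physician",
          class = "htngap_validation_error")
  }
  if (!(adult_fraction > 0 && adult_fraction <= 1)) {
    abort("adult_fraction must be in (0, 1]", class = "htngap_validation_error")
  }

  pick <- function(tbl, value_col, new_name) {
    if (is.null(tbl)) return(tibble(iso3 = character(), "{new_name}" := numeric()))
    if (anyDuplicated(tbl$iso3)) {
      abort(paste0("duplicate iso3 rows in ", new_name, " table"),
            class = "htngap_validation_error")
    }
    tbl |>
      dplyr::select("iso3", !!new_name := dplyr::all_of(value_col))
  }

  base <- pick(densities$physician, "density", "density_physician")

  if (anyDuplicated(population$iso3)) {
    abort("duplicate iso3 rows in population table", class = "htngap_validation_error")
  }
  if (anyDuplicated(prevalence$iso3)) {
    abort("duplicate iso3 rows in prevalence table", class = "htngap_validation_error")
  }
  if (anyDuplicated(income$iso3)) {
    abort("duplicate iso3 rows in income table", class = "htngap_validation_error")
  }

  inc <- as_tibble(income)
  if (!"income_group" %in% names(inc)) {
    if (!"gni_per_capita" %in% names(inc)) {
      abort("income table needs an income_group or gni_per_capita column",
            class = "htngap_validation_error")
    }
    inc$income_group <- classify_income(inc$gni_per_capita, thresholds)
  }
  inc <- dplyr::select(inc, "iso3", "income_group")

  pop <- as_tibble(population)
  if (!"name" %in% names(pop)) pop$name <- pop$iso3
  if (!"population_eligible" %in% names(pop)) {
    pop$population_eligible <- pop$population_total * adult_fraction
  }
  pop <- dplyr::select(pop, "iso3", "name", "population_total", "population_eligible")

  # union of every country seen anywhere, so drops can be reported
  all_iso <- sort(unique(c(base$iso3, prevalence$iso3, pop$iso3, inc$iso3)))
  merged <- tibble(iso3 = all_iso) |>
    dplyr::left_join(pop, by = "iso3") |>
    dplyr::left_join(inc, by = "iso3") |>
    dplyr::left_join(base, by = "iso3") |>
    dplyr::left_join(pick(densities$nurse, "density", "density_nurse"), by = "iso3") |>
    dplyr::left_join(pick(densities$pharmacist, "density", "density_pharmacist"), by = "iso3") |>
    dplyr::left_join(pick(densities$chw, "density", "density_chw"), by = "iso3") |>
    dplyr::left_join(prevalence, by = "iso3")

  reason <- dplyr::case_when(
    is.na(merged$density_physician) ~ "no physician density",
    is.na(merged$prevalence) ~ "no prevalence estimate",
    is.na(merged$population_total) ~ "no population count",
    is.na(merged$income_group) ~ "no income classification",
    TRUE ~ NA_character_
  )
  dropped <- merged$iso3[!is.na(reason)]
  if (!quiet && length(dropped) > 0) {
    for (i in which(!is.na(reason))) {
      log_msg("WARN", "dropping ", merged$iso3[i], ": ", reason[i])
    }
  }

  kept <- merged[is.na(reason), , drop = FALSE]
  if (nrow(kept) == 0) {
    abort("no country satisfies the inclusion rule", class = "htngap_assembly_error")
  }
  kept |>
    dplyr::mutate(name = dplyr::coalesce(.data$name, .data$iso3)) |>
    dplyr::select(dplyr::all_of(dataset_columns())) |>
    validate_dataset()
}
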