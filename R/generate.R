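# Synthetic country-level data generator. Emulates the statistical
# structure of the real inputs — 199 countries split across income groups,
# group-conditional provider densities and hypertension prevalence, and
# community-health-worker data missing for roughly half of countries — so
# the whole pipeline is testable without any download.

# Group-level density means per 10 000 (LIC -> HIC). The per-group spread is
# not published, so each cadre's pooled coefficient of variation
# (physicians 17.4/19.2, nurses 54.1/47.3, pharmacists 4.7/3.9) is applied
# to its group mean; nurses' CV exceeds 1, so zero-truncation is active.
default_density_params <- function() {
  groups <- income_levels()
  phys <- c(1.9, 7.8, 20.7, 33.8)
  nurse <- c(14.8, 20.8, 40.8, 88.7)
  pharm <- c(0.6, 1.7, 3.1, 8.0)
  cv <- c(physician = 17.4 / 19.2, nurse = 54.1 / 47.3, pharmacist = 4.7 / 3.9)
  dplyr::bind_rows(
    tibble(income_group = groups, provider = "physician",
           mean = phys, sd = phys * cv[["physician"]]),
    tibble(income_group = groups, provider = "nurse",
           mean = nurse, sd = nurse * cv[["nurse"]]),
    tibble(income_group = groups, provider = "pharmacist",
           mean = pharm, sd = pharm * cv[["pharmacist"]]),
    # CHW density is only reported pooled (3.4 +/- 7.3, maximum 44.9), so the
    # same parameters apply in every group; the draw is upper-clipped at the
    # observed maximum in generate_dataset().
    tibble(income_group = groups, provider = "chw", mean = 3.4, sd = 7.3)
  )
}

# Group prevalence mean (SD) on the percent scale, LIC -> HIC.
default_prevalence_params <- function() {
  tibble(
    income_group = income_levels(),
    mean = c(36.7, 36.1, 40.3, 36.2),
    sd = c(4.8, 5.7, 6.7, 7.0),
    ci_half_width = 6
  )
}

#' Configuration for the synthetic country-dataset generator
#'
#' Defaults reproduce the study conditions of the source datasets: 199
#' countries split 61/64/49/25 across HIC/UMIC/LMIC/LIC; zero-truncated
#' normal provider densities with the observed group means; normal
#' prevalence on the percent scale with the observed group means and SDs,
#' clipped to (5, 80); a fixed 6-percentage-point interval half-width; and
#' community-health-worker density missing with probability `1 - 96/199`.
#'
#' @param n_countries_by_group named integer vector of country counts per
#'   income group (names from `LIC`, `LMIC`, `UMIC`, `HIC`)
#' @param density_params data frame with columns `income_group`, `provider`
#'   (`physician`, `nurse`, `pharmacist`, `chw`), `mean`, `sd` — parameters,
#'   per 10 000 population, of the pre-truncation normal each density is
#'   drawn from
#' @param prevalence_params data frame with columns `income_group`, `mean`,
#'   `sd`, `ci_half_width`, all on the percent scale
#' @param chw_missing_prob probability a country's CHW density is missing
#' @param population_range length-2 numeric, min and max total population;
#'   populations are drawn log-uniformly between them
#' @param adult_fraction share of total population eligible for the
#'   prevalence denominator
#' @param seed integer seed; fully determines the generated dataset
#'
#' @return a list of class `generator_config`
#' @examples
#' cfg <- generator_config(seed = 42)
#' d <- generate_dataset(cfg)
#' dplyr::count(d, income_group)
#' @export
generator_config <- function(n_countries_by_group = c(HIC = 61, UMIC = 64, LMIC = 49, LIC = 25),
                             density_params = default_density_params(),
                             prevalence_params = default_prevalence_params(),
                             chw_missing_prob = 1 - 96 / 199,
                             population_range = c(1e4, 1.4e9),
                             adult_fraction = 0.6,
                             seed = 1L) {
  bad <- function(msg) abort(msg, class = "htngap_validation_error")

  if (is.null(names(n_countries_by_group)) ||
      !all(names(n_countries_by_group) %in% income_levels())) {
    bad("n_countries_by_group must be named with income-group labels")
  }
  if (any(n_countries_by_group < 0) || sum(n_countries_by_group) < 1) {
    bad("n_countries_by_group must be non-negative with at least one country")
  }
  density_params <- as_tibble(density_params)
  if (!all(c("income_group", "provider", "mean", "sd") %in% names(density_params))) {
    bad("density_params needs income_group, provider, mean, sd columns")
  }
  if (any(density_params$mean < 0) || any(density_params$sd < 0)) {
    bad("density means and sds must be non-negative")
  }
  prevalence_params <- as_tibble(prevalence_params)
  if (!all(c("income_group", "mean", "sd", "ci_half_width") %in% names(prevalence_params))) {
    bad("prevalence_params needs income_group, mean, sd, ci_half_width columns")
  }
  if (any(prevalence_params$mean < 0) || any(prevalence_params$sd < 0) ||
      any(prevalence_params$ci_half_width < 0)) {
    bad("prevalence parameters must be non-negative")
  }
  if (!(chw_missing_prob >= 0 && chw_missing_prob <= 1)) {
    bad("chw_missing_prob must be in [0, 1]")
  }
  if (length(population_range) != 2 || population_range[1] <= 0 ||
      population_range[1] > population_range[2]) {
    bad("population_range must be (min, max) with 0 < min <= max")
  }
  if (!(adult_fraction > 0 && adult_fraction <= 1)) {
    bad("adult_fraction must be in (0, 1]")
  }
  seed <- as.integer(seed)
  if (is.na(seed)) bad("seed must be an integer")

  # every group used for generation must have parameters
  used <- names(n_countries_by_group)[n_countries_by_group > 0]
  for (prov in c("physician", "nurse", "pharmacist", "chw")) {
    have <- density_params$income_group[density_params$provider == prov]
    if (!all(used %in% have)) {
      bad(paste0("density_params missing group rows for provider ", prov))
    }
  }
  if (!all(used %in% prevalence_params$income_group)) {
    bad("prevalence_params missing rows for some income group")
  }

  structure(
    list(
      n_countries_by_group = n_countries_by_group,
      density_params = density_params,
      prevalence_params = prevalence_params,
      chw_missing_prob = chw_missing_prob,
      population_range = as.numeric(population_range),
      adult_fraction = adult_fraction,
      seed = seed
    ),
    class = "generator_config"
  )
}

# Maximum CHW density retained, per 10 000 (highest value observed in the
# source data).
CHW_DENSITY_CAP <- 44.9

#' Generate a synthetic country dataset
#'
#' Draws one country record per configured slot: income group assigned by
#' the configured counts, total population log-uniform over the configured
#' range, provider densities from zero-truncated normals with the group's
#' parameters (CHW additionally capped at 44.9 per 10 000 and set missing
#' with the configured probability), and prevalence from a normal on the
#' percent scale clipped to (5, 80) with symmetric interval bounds clipped
#' to `[0, 1]`. Deterministic given `config$seed`.
#'
#' @param config a [generator_config()] object
#' @return a validated country dataset tibble (see [validate_dataset()]),
#'   rows ordered LIC to HIC then by iso3
#' @examples
#' d <- generate_dataset(generator_config(seed = 7))
#' nrow(d)
#' chw_coverage(d)
#' @export
generate_dataset <- function(config = generator_config()) {
  if (!inherits(config, "generator_config")) {
    abort("config must be a generator_config object", class = "htngap_validation_error")
  }
  counts <- config$n_countries_by_group[income_levels()]
  counts[is.na(counts)] <- 0L
  n <- sum(counts)
  group <- factor(rep(income_levels(), counts), levels = income_levels())

  set.seed(config$seed)

  pop <- exp(runif(n, log(config$population_range[1]), log(config$population_range[2])))

  dp <- function(provider) {
    par <- config$density_params[config$density_params$provider == provider, ]
    m <- par$mean[match(group, par$income_group)]
    s <- par$sd[match(group, par$income_group)]
    rtruncnorm0(n, m, s)
  }
  d_phys <- dp("physician")
  d_nurse <- dp("nurse")
  d_pharm <- dp("pharmacist")
  d_chw <- pmin(dp("chw"), CHW_DENSITY_CAP)
  d_chw[runif(n) < config$chw_missing_prob] <- NA_real_

  pp <- config$prevalence_params
  pm <- pp$mean[match(group, pp$income_group)]
  ps <- pp$sd[match(group, pp$income_group)]
  hw <- pp$ci_half_width[match(group, pp$income_group)]
  prev_pct <- pmin(pmax(rnorm(n, pm, ps), 5), 80)
  prev <- prev_pct / 100
  prev_lo <- pmax(prev - hw / 100, 0)
  prev_hi <- pmin(prev + hw / 100, 1)

  iso3 <- synthetic_iso3(n)
  tibble(
    iso3 = iso3,
    name = paste("Country", iso3),
    population_total = pop,
    population_eligible = pop * config$adult_fraction,
    income_group = group,
    density_physician = d_phys,
    density_nurse = d_nurse,
    density_pharmacist = d_pharm,
    density_chw = d_chw,
    prevalence = prev,
    prevalence_lo = prev_lo,
    prevalence_hi = prev_hi
  ) |>
    validate_dataset()
}

#' Read a generator configuration from a YAML or JSON file
#'
#' Every field is optional; anything absent falls back to the
#' [generator_config()] default. `density_params` and `prevalence_params`
#' may be given as lists of records (one mapping per row).
#'
#' @param path path to a YAML (or JSON, which YAML subsumes) file
#' @param seed optional seed overriding both the file and the default
#' @return a `generator_config` object
#' @export
read_generator_config <- function(path, seed = NULL) {
  raw <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(raw$n_countries_by_group)) {
    args$n_countries_by_group <- unlist(raw$n_countries_by_group)
  }
  for (fld in c("chw_missing_prob", "adult_fraction", "seed")) {
    if (!is.null(raw[[fld]])) args[[fld]] <- raw[[fld]]
  }
  if (!is.null(raw$population_range)) {
    args$population_range <- as.numeric(unlist(raw$population_range))
  }
  for (fld in c("density_params", "prevalence_params")) {
    if (!is.null(raw[[fld]])) {
      args[[fld]] <- dplyr::bind_rows(lapply(raw[[fld]], as_tibble))
    }
  }
  if (!is.null(seed)) args$seed <- seed
  do.call(generator_config, args)
}
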