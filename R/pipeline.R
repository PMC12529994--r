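# Reproducible end-to-end pipeline: dataset in (file or synthetic),
# per-country and summary tables out, plus a manifest that records exactly
# what produced them. Identical inputs, parameters and seed give
# byte-identical outputs.

#' Run configuration
#'
#' Bundles everything one pipeline run depends on. `input = NULL` means a
#' synthetic dataset is generated from `generator` (whose seed may be
#' overridden by `seed`).
#'
#' @param input path to a canonical dataset CSV, or `NULL` for synthetic data
#' @param outdir output directory (created if absent)
#' @param scenarios a [scenario_grid()] tibble; defaults to the full grid
#' @param params a [capacity_params()] object
#' @param generator a [generator_config()] for synthetic runs
#' @param seed overrides `generator$seed` when not `NULL`
#' @param log_level `"info"`, `"warn"` or `"quiet"`
#' @return a list of class `run_config`
#' @export
run_config <- function(input = NULL, outdir = ".", scenarios = scenario_grid(),
                       params = capacity_params(),
                       generator = generator_config(),
                       seed = NULL, log_level = "info") {
  if (nrow(scenarios) == 0) {
    abort("scenario subset must be non-empty", class = "htngap_validation_error")
  }
  if (!is.null(seed)) {
    generator$seed <- as.integer(seed)
  }
  structure(
    list(input = input, outdir = outdir, scenarios = scenarios,
         params = params, generator = generator, log_level = log_level),
    class = "run_config"
  )
}

#' Read a run configuration from YAML
#'
#' Recognised top-level keys, all optional: `input`, `outdir`, `seed`,
#' `log_level`, `scenarios` (with `visits_per_year`, `patients_per_day`,
#' `care_model` lists), `params` (capacity parameter overrides) and
#' `generator` (passed to [generator_config()] via its reader fields).
#' Arguments given directly to this function override file values.
#'
#' @param path YAML (or JSON) file path
#' @param ... overrides forwarded to [run_config()]
#' @return a `run_config` object
#' @export
read_run_config <- function(path, ...) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  args <- list(...)
  take <- function(key) if (is.null(args[[key]])) raw[[key]] else args[[key]]

  scen <- raw$scenarios
  scenarios <- args$scenarios %||% if (is.null(scen)) {
    scenario_grid()
  } else {
    scenario_grid(
      visits_per_year = unlist(scen$visits_per_year) %||% c(12, 6, 3, 1),
      patients_per_day = unlist(scen$patients_per_day) %||% c(20, 10),
      care_model = unlist(scen$care_model) %||% care_model_levels()
    )
  }
  params <- args$params %||% do.call(capacity_params, raw$params %||% list())
  generator <- args$generator %||% if (is.null(raw$generator)) {
    generator_config()
  } else {
    gen_file <- tempfile(fileext = ".yaml")
    on.exit(unlink(gen_file), add = TRUE)
    yaml::write_yaml(raw$generator, gen_file)
    read_generator_config(gen_file)
  }
  run_config(
    input = take("input"), outdir = take("outdir") %||% ".",
    scenarios = scenarios, params = params, generator = generator,
    seed = take("seed"), log_level = take("log_level") %||% "info"
  )
}

pipeline_log <- function(config, level, ...) {
  rank <- c(info = 1, warn = 2, quiet = 3)
  if (rank[[config$log_level %||% "info"]] <= rank[[level]]) {
    log_msg(toupper(level), ...)
  }
}

#' Run the pipeline
#'
#' Loads (or generates) the country dataset, computes the per-country gap
#' table over the configured scenario grid, aggregates it, and writes four
#' artifacts to `config$outdir`: `dataset.csv` (the dataset used),
#' `results_country.csv`, `results_summary.csv`, JSON copies of both, and
#' `manifest.json` recording input checksums, every parameter, the
#' scenario labels and the package version. All tables are computed before
#' anything is written, so a failure leaves no partial outputs.
#'
#' @param config a [run_config()] object
#' @return an `htn_gap_analysis` object, invisibly; called for its file
#'   outputs
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))

  if (is.null(config$input)) {
    pipeline_log(config, "info", "generating synthetic dataset (seed ",
                 config$generator$seed, ")")
    data <- generate_dataset(config$generator)
    input_record <- list(type = "synthetic", seed = config$generator$seed)
  } else {
    if (!file.exists(config$input)) {
      abort(paste0("input file does not exist: ", config$input),
            class = "htngap_input_error")
    }
    pipeline_log(config, "info", "reading dataset from ", config$input)
    data <- read_dataset(config$input)
    input_record <- list(
      type = "file", path = config$input,
      md5 = unname(tools::md5sum(config$input))
    )
  }

  pipeline_log(config, "info", "computing ", nrow(config$scenarios),
               " scenario cells over ", nrow(data), " countries")
  fit <- gap_analysis(data, config$scenarios, config$params)

  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(config$outdir, c(
    dataset = "dataset.csv",
    country = "results_country.csv",
    summary = "results_summary.csv",
    country_json = "results_country.json",
    summary_json = "results_summary.json",
    manifest = "manifest.json"
  ))
  names(paths) <- c("dataset", "country", "summary",
                    "country_json", "summary_json", "manifest")

  write_dataset(data, paths[["dataset"]])
  readr::write_csv(fit$gaps, paths[["country"]], na = "")
  readr::write_csv(fit$summary, paths[["summary"]], na = "")
  jsonlite::write_json(fit$gaps, paths[["country_json"]],
                       dataframe = "rows", digits = NA, na = "null")
  jsonlite::write_json(fit$summary, paths[["summary_json"]],
                       dataframe = "rows", digits = NA, na = "null")

  manifest <- list(
    tool = "htngap",
    version = as.character(utils::packageVersion("htngap")),
    input = input_record,
    params = unclass(config$params),
    scenarios = config$scenarios$scenario,
    n_countries = nrow(data),
    chw_coverage = chw_coverage(data),
    outputs = lapply(
      list(dataset = paths[["dataset"]], results_country = paths[["country"]],
           results_summary = paths[["summary"]]),
      function(p) list(file = basename(p), md5 = unname(tools::md5sum(p)))
    )
  )
  jsonlite::write_json(manifest, paths[["manifest"]],
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  pipeline_log(config, "info", "wrote ", length(paths), " artifacts to ",
               config$outdir)
  invisible(fit)
}

#' Summarise a finished run in plain text
#'
#' Reads the per-country and summary tables from a pipeline output
#' directory and prints, per scenario cell: the global cumulative gap with
#' its interval (millions of visits/year), each income group's cumulative
#' gap and percentage gap, the number of countries in surplus, and the
#' extreme countries. Every number is recomputable from
#' `results_country.csv` alone.
#'
#' @param indir directory written by [run_pipeline()]
#' @param sign `"deficit_positive"` (default) or `"surplus_positive"`,
#'   flipping the sign used for display only
#' @return the report, invisibly, as a character vector of lines
#' @export
summarize_run <- function(indir, sign = c("deficit_positive", "surplus_positive")) {
  sign <- match.arg(sign)
  flip <- if (sign == "deficit_positive") 1 else -1
  country_path <- file.path(indir, "results_country.csv")
  summary_path <- file.path(indir, "results_summary.csv")
  if (!file.exists(country_path) || !file.exists(summary_path)) {
    abort(paste0("no pipeline artifacts found in ", indir),
          class = "htngap_format_error")
  }
  gaps <- readr::read_csv(country_path, show_col_types = FALSE, progress = FALSE)
  summ <- readr::read_csv(summary_path, show_col_types = FALSE, progress = FALSE)
  needed <- c("iso3", "scenario", "gap", "is_surplus")
  if (!all(needed %in% names(gaps)) || !"cumulative_gap" %in% names(summ)) {
    abort("artifact tables are malformed", class = "htngap_format_error")
  }

  lines <- character()
  say <- function(...) lines <<- c(lines, paste0(...))
  mil <- function(x) sprintf("%.1f", flip * x / 1e6)

  say("Hypertension care capacity gap report")
  say("  sign convention: positive = ",
      if (sign == "deficit_positive") "deficit (demand exceeds supply)"
      else "surplus (supply exceeds demand)")
  for (cell in unique(summ$scenario)) {
    s <- summ[summ$scenario == cell, ]
    g <- gaps[gaps$scenario == cell, ]
    glob <- s[s$income_group == "GLOBAL", ]
    say("")
    say("scenario ", cell, " (", glob$visits_per_year, " visits/yr, ",
        glob$patients_per_day, " patients/day, ", glob$care_model, ")")
    say("  global gap: ", mil(glob$cumulative_gap), " M visits/yr [",
        mil(glob$cumulative_gap_lo), ", ", mil(glob$cumulative_gap_hi), "]")
    for (grp in income_levels()) {
      r <- s[s$income_group == grp, ]
      if (nrow(r) == 0) next
      pct <- gap_percentage(r$cumulative_demand, r$cumulative_supply)
      say("    ", grp, ": ", mil(r$cumulative_gap), " M visits/yr (",
          if (is.na(pct)) "gap % undefined" else sprintf("%.0f%%", flip * pct),
          "), ", r$n_surplus, "/", r$n_countries, " countries in surplus")
    }
    say("  surplus countries: ", count_surplus_countries(g), "/", nrow(g))
    ex <- rank_extremes(g)
    if (!is.null(ex$largest_deficit)) {
      say("  largest deficit: ", ex$largest_deficit$iso3, " (",
          mil(ex$largest_deficit$gap), " M visits/yr)")
    }
    if (!is.null(ex$largest_surplus)) {
      say("  largest surplus: ", ex$largest_surplus$iso3, " (",
          mil(ex$largest_surplus$gap), " M visits/yr)")
    }
  }
  cat(lines, sep = "\n")
  cat("\n")
  invisible(lines)
}
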