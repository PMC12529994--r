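# Readers for the external table layouts: World Bank indicator extracts
# (long or wide), NCD-RisC-style prevalence tables, and the package's own
# canonical country dataset CSV.

# Lower-case, squash punctuation/whitespace to "_": "Country Code" -> "country_code".
clean_names <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("[^a-z0-9]+", "_", x)
  gsub("^_|_$", "", x)
}

# First column of `df` whose cleaned name is in `candidates`, else NULL.
find_column <- function(df, candidates) {
  hit <- match(candidates, clean_names(names(df)))
  hit <- hit[!is.na(hit)]
  if (length(hit) == 0) NULL else names(df)[hit[1]]
}

find_iso3_column <- function(df, path) {
  col <- find_column(df, c("iso3", "iso3c", "country_code", "code", "countrycode"))
  if (is.null(col)) {
    # fall back to any column that looks like 3-letter codes throughout
    looks_iso3 <- vapply(df, function(v) {
      is.character(v) && all(grepl("^[A-Za-z]{3}$", v[!is.na(v)])) && any(!is.na(v))
    }, logical(1))
    if (any(looks_iso3)) col <- names(df)[which(looks_iso3)[1]]
  }
  if (is.null(col)) {
    abort(paste0("no country-code (iso3) column found in ", path))
  }
  col
}

read_delim_guess <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("input file does not exist: ", path), class = "htngap_input_error")
  }
  out <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                    na = c("", "NA", "..", "N/A")),
    error = function(e) {
      abort(paste0("could not read ", path, ": ", conditionMessage(e)),
            class = "htngap_input_error")
    }
  )
  if (ncol(out) < 2) {
    abort(paste0("could not parse a table from ", path),
          class = "htngap_input_error")
  }
  out
}

#' Read a World Bank-style provider-density table
#'
#' Accepts either the long indicator layout (country, code, year, value —
#' one row per country-year) or the wide layout (one column per year). For
#' each country the most recent non-missing value is kept; countries with no
#' value in any year are absent from the result.
#'
#' @param path path to a delimited text file
#' @param indicator_name if the file carries several indicators in long
#'   layout (an `indicator_name` column), keep only rows matching this name
#'
#' @return tibble with columns `iso3`, `density` (providers per 10 000
#'   population) and `year`
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("code,year,value", "IND,2019,7.0", "IND,2021,7.3"), f)
#' read_density_table(f)
#' @export
read_density_table <- function(path, indicator_name = NULL) {
  df <- read_delim_guess(path)
  iso_col <- find_iso3_column(df, path)

  ind_col <- find_column(df, c("indicator_name", "indicator"))
  if (!is.null(indicator_name) && !is.null(ind_col)) {
    df <- df[df[[ind_col]] == indicator_name, , drop = FALSE]
  }

  year_col <- find_column(df, c("year", "date", "time"))
  value_col <- find_column(df, c("value", "density"))

  if (!is.null(year_col) && !is.null(value_col)) {
    long <- tibble(
      iso3 = toupper(df[[iso_col]]),
      year = as.integer(df[[year_col]]),
      density = as.numeric(df[[value_col]])
    )
  } else {
    # wide layout: year columns named e.g. "2018", "2018 [YR2018]", "X2019"
    yr_like <- grepl("^x?_?([0-9]{4})", clean_names(names(df)))
    yr_cols <- names(df)[yr_like]
    if (length(yr_cols) == 0) {
      abort(paste0("no year/value columns recognised in ", path),
            class = "htngap_input_error")
    }
    long <- df |>
      dplyr::select(dplyr::all_of(c(iso_col, yr_cols))) |>
      tidyr::pivot_longer(-dplyr::all_of(iso_col),
                          names_to = "year", values_to = "density") |>
      dplyr::mutate(
        iso3 = toupper(.data[[iso_col]]),
        year = as.integer(sub("^x?_?([0-9]{4}).*$", "\\1", clean_names(.data$year))),
        density = as.numeric(.data$density)
      ) |>
      dplyr::select("iso3", "year", "density")
  }

  long <- dplyr::filter(long, !is.na(.data$iso3), !is.na(.data$year))
  bad <- dplyr::filter(long, !is.na(.data$density) & .data$density < 0)
  if (nrow(bad) > 0) {
    abort(paste0("negative density for ", bad$iso3[1], " in year ", bad$year[1]),
          class = "htngap_validation_error")
  }

  long |>
    dplyr::filter(!is.na(.data$density)) |>
    dplyr::group_by(.data$iso3) |>
    dplyr::slice_max(.data$year, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("iso3", "density", "year") |>
    dplyr::arrange(.data$iso3)
}

#' Read an NCD-RisC-style prevalence table
#'
#' Expects one row per country with a point estimate and 95% interval
#' bounds. Rows whose point estimate exceeds 1 are interpreted as percent
#' and divided by 100, so files on either scale load identically.
#'
#' @param path path to a delimited text file with country code, point,
#'   lower and upper columns
#'
#' @return tibble with columns `iso3`, `prevalence`, `prevalence_lo`,
#'   `prevalence_hi`, all proportions in `[0, 1]`
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("code,prevalence,lower,upper", "NPL,37.5,30.9,44.1"), f)
#' read_prevalence_table(f)
#' @export
read_prevalence_table <- function(path) {
  df <- read_delim_guess(path)
  iso_col <- find_iso3_column(df, path)

  point_col <- find_column(df, c("prevalence", "point", "estimate", "mean", "value"))
  lo_col <- find_column(df, c("prevalence_lo", "lower", "lo", "lower_95", "ci_lower", "l95"))
  hi_col <- find_column(df, c("prevalence_hi", "upper", "hi", "upper_95", "ci_upper", "u95"))
  if (is.null(point_col) || is.null(lo_col) || is.null(hi_col)) {
    # positional fallback: first three numeric columns are point, lower, upper
    num_cols <- names(df)[vapply(df, is.numeric, logical(1))]
    if (length(num_cols) < 3) {
      abort(paste0("could not locate point/lower/upper columns in ", path),
            class = "htngap_input_error")
    }
    point_col <- num_cols[1]; lo_col <- num_cols[2]; hi_col <- num_cols[3]
  }

  out <- tibble(
    iso3 = toupper(df[[iso_col]]),
    prevalence = as.numeric(df[[point_col]]),
    prevalence_lo = as.numeric(df[[lo_col]]),
    prevalence_hi = as.numeric(df[[hi_col]])
  ) |>
    dplyr::filter(!is.na(.data$prevalence))

  if (any(out$prevalence > 100 | out$prevalence_hi > 100, na.rm = TRUE)) {
    abort("prevalence values above 100 are not interpretable on any scale",
          class = "htngap_validation_error")
  }
  pct <- !is.na(out$prevalence) & out$prevalence > 1
  out[pct, c("prevalence", "prevalence_lo", "prevalence_hi")] <-
    out[pct, c("prevalence", "prevalence_lo", "prevalence_hi")] / 100

  bad <- with(out, prevalence_lo > prevalence | prevalence > prevalence_hi |
                prevalence_lo < 0 | prevalence_hi > 1)
  if (any(bad, na.rm = TRUE)) {
    abort(paste0("interval ordering violated for ", out$iso3[which(bad)[1]],
                 " (need 0 <= lower <= point <= upper <= 1)"),
          class = "htngap_validation_error")
  }
  dplyr::arrange(out, .data$iso3)
}

# Canonical country-dataset CSV -----------------------------------------

dataset_columns <- function() {
  c("iso3", "name", "population_total", "population_eligible", "income_group",
    "density_physician", "density_nurse", "density_pharmacist", "density_chw",
    "prevalence", "prevalence_lo", "prevalence_hi")
}

#' Write / read the canonical country dataset CSV
#'
#' One row per country with population, income group, provider densities
#' per 10 000, and hypertension prevalence with its 95% interval. Missing
#' optional densities are empty cells. `read_dataset()` validates every
#' invariant on load, so a round trip reproduces the dataset exactly.
#'
#' @param data a country dataset tibble (see [validate_dataset()])
#' @param path file path
#' @return `write_dataset()` returns `path` invisibly; `read_dataset()`
#'   returns a validated dataset tibble
#' @examples
#' d <- generate_dataset(generator_config(seed = 1))
#' f <- tempfile(fileext = ".csv")
#' write_dataset(d, f)
#' identical(read_dataset(f), d)
#' @export
write_dataset <- function(data, path) {
  data <- validate_dataset(data)
  readr::write_csv(data, path, na = "")
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  df <- read_delim_guess(path)
  missing_cols <- setdiff(dataset_columns(), names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("dataset file ", path, " lacks columns: ",
                 paste(missing_cols, collapse = ", ")),
          class = "htngap_input_error")
  }
  df |>
    dplyr::select(dplyr::all_of(dataset_columns())) |>
    dplyr::mutate(
      iso3 = as.character(.data$iso3),
      name = as.character(.data$name),
      income_group = factor(.data$income_group, levels = income_levels()),
      dplyr::across(!c("iso3", "name", "income_group"), as.numeric)
    ) |>
    validate_dataset()
}
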