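# One-call analysis object tying the stages together, with broom-style
# accessors.

#' Run the full gap analysis on a country dataset
#'
#' Convenience wrapper: validates the dataset, computes per-country gaps
#' over the scenario grid, and aggregates them by income group and
#' globally. The result supports [tidy()] (per-country rows), [glance()]
#' (one-row overview), [summary()] and [autoplot()].
#'
#' @param data a country dataset tibble
#' @inheritParams compute_gaps
#' @return an object of class `htn_gap_analysis`: a list with `data`,
#'   `scenarios`, `params`, `gaps` (per-country rows) and `summary`
#'   (group/global rows)
#' @examples
#' fit <- gap_analysis(generate_dataset(generator_config(seed = 1)))
#' glance(fit)
#' tidy(fit)
#' @export
gap_analysis <- function(data, scenarios = scenario_grid(), params = capacity_params()) {
  data <- validate_dataset(data)
  gaps <- compute_gaps(data, scenarios, params)
  structure(
    list(
      data = data,
      scenarios = scenarios,
      params = params,
      gaps = gaps,
      summary = summarize_gaps(gaps, data)
    ),
    class = "htn_gap_analysis"
  )
}

#' @export
print.htn_gap_analysis <- function(x, ...) {
  base <- x$summary |>
    dplyr::filter(.data$income_group == "GLOBAL")
  cat("<htn_gap_analysis>\n")
  cat("  countries: ", nrow(x$data),
      " (CHW data for ", chw_coverage(x$data), ")\n", sep = "")
  cat("  scenarios: ", nrow(x$scenarios), " cells\n", sep = "")
  cat("  global cumulative gap (millions of visits/year):\n")
  shown <- head(dplyr::arrange(base, dplyr::desc(.data$visits_per_year)), 6)
  for (i in seq_len(nrow(shown))) {
    cat(sprintf("    %-28s %10.1f [%.1f, %.1f]\n",
                shown$scenario[i], shown$cumulative_gap[i] / 1e6,
                shown$cumulative_gap_lo[i] / 1e6, shown$cumulative_gap_hi[i] / 1e6))
  }
  if (nrow(base) > nrow(shown)) {
    cat("    ... and ", nrow(base) - nrow(shown), " more cells\n", sep = "")
  }
  invisible(x)
}

#' Tidy a gap analysis into per-country rows
#'
#' @param x an `htn_gap_analysis` object
#' @param ... unused
#' @return the per-country gap tibble (see [compute_gaps()])
#' @export
tidy.htn_gap_analysis <- function(x, ...) {
  x$gaps
}

#' One-row overview of a gap analysis
#'
#' Reports the dataset size and, for the high-demand base cell (the largest
#' visit schedule at the highest throughput), the global cumulative gap in
#' millions of visits/year under physician-only and team-based care and the
#' number of surplus countries under team-based care.
#'
#' @param x an `htn_gap_analysis` object
#' @param ... unused
#' @return a one-row tibble
#' @export
glance.htn_gap_analysis <- function(x, ...) {
  g <- x$summary |> dplyr::filter(.data$income_group == "GLOBAL")
  base_cell <- function(model) {
    g |>
      dplyr::filter(.data$care_model == model,
                    .data$visits_per_year == max(.data$visits_per_year),
                    .data$patients_per_day == max(.data$patients_per_day))
  }
  phys <- base_cell("physician_only")
  team <- base_cell("team")
  tibble(
    n_countries = nrow(x$data),
    n_scenarios = nrow(x$scenarios),
    chw_coverage = chw_coverage(x$data),
    gap_physician_only_m = if (nrow(phys) == 1) phys$cumulative_gap / 1e6 else NA_real_,
    gap_team_m = if (nrow(team) == 1) team$cumulative_gap / 1e6 else NA_real_,
    n_surplus_team = if (nrow(team) == 1) team$n_surplus else NA_integer_
  )
}

#' Plot cumulative gaps by income group
#'
#' Bar chart of the cumulative visit gap (millions per year) by income
#' group, faceted by care model, for one throughput level, with error bars
#' from the prevalence-propagated interval. Positive bars are deficits by
#' default; set `sign = "surplus_positive"` to flip the presentation.
#'
#' @param object an `htn_gap_analysis` object
#' @param patients_per_day which throughput level to show (default: highest)
#' @param sign `"deficit_positive"` (default) or `"surplus_positive"`
#' @param ... unused
#' @return a ggplot object
#' @export
autoplot.htn_gap_analysis <- function(object,
                                      patients_per_day = NULL,
                                      sign = c("deficit_positive", "surplus_positive"),
                                      ...) {
  sign <- match.arg(sign)
  flip <- if (sign == "deficit_positive") 1 else -1
  d <- object$summary |>
    dplyr::filter(.data$income_group != "GLOBAL")
  ppd <- patients_per_day %||% max(d$patients_per_day)
  d <- d |>
    dplyr::filter(.data$patients_per_day == ppd) |>
    dplyr::mutate(
      gap_m = flip * .data$cumulative_gap / 1e6,
      gap_lo_m = flip * .data$cumulative_gap_lo / 1e6,
      gap_hi_m = flip * .data$cumulative_gap_hi / 1e6,
      visits = factor(.data$visits_per_year,
                      levels = sort(unique(.data$visits_per_year), decreasing = TRUE))
    )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$income_group, y = .data$gap_m,
                                  fill = .data$visits)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$gap_lo_m, ymax = .data$gap_hi_m),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25, linewidth = 0.3
    ) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$care_model)) +
    ggplot2::labs(
      x = "Income group",
      y = if (sign == "deficit_positive") {
        "Cumulative visit gap (millions/year; positive = deficit)"
      } else {
        "Cumulative visit balance (millions/year; positive = surplus)"
      },
      fill = "Visits/patient/year",
      title = sprintf("Hypertension visit gap at %s patients/provider/day", ppd)
    ) +
    ggplot2::theme_minimal()
}
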