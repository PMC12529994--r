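test_that("per-country gap matches the hand-worked toy country", {
  # 10^7 eligible (and total) people, prevalence 0.35, physician density 10:
  # demand = 12 x 0.35 x 1e7 = 42M; supply = (10/1e4) x 1e7 x 400 = 4M
  d <- tibble::tibble(
    iso3 = "TOY", name = "Toyland",
    population_total = 1e7, population_eligible = 1e7,
    income_group = factor("LMIC", levels = c("LIC", "LMIC", "UMIC", "HIC")),
    density_physician = 10, density_nurse = NA_real_,
    density_pharmacist = NA_real_, density_chw = NA_real_,
    prevalence = 0.35, prevalence_lo = 0.35, prevalence_hi = 0.35
  )
  g <- compute_gaps(d, scenario_grid(visits_per_year = 12, patients_per_day = 20,
                                     care_model = "physician_only"))
  expect_equal(g$demand, 42e6)
  expect_equal(g$supply, 4e6)
  expect_equal(g$gap, 38e6)
  expect_false(g$is_surplus)
  # degenerate prevalence interval collapses the gap interval
  expect_equal(g$gap_lo, g$gap)
  expect_equal(g$gap_hi, g$gap)
})

test_that("a balanced country has zero gap and is not a surplus", {
  d <- tibble::tibble(
    iso3 = "BAL", name = "Balance",
    population_total = 1e6, population_eligible = 1e6,
    income_group = factor("HIC", levels = c("LIC", "LMIC", "UMIC", "HIC")),
    # supply = (d/1e4) * 1e6 * 400 must equal demand = 12 * 0.4 * 1e6 = 4.8e6
    # => density = 120
    density_physician = 120, density_nurse = NA_real_,
    density_pharmacist = NA_real_, density_chw = NA_real_,
    prevalence = 0.4, prevalence_lo = 0.4, prevalence_hi = 0.4
  )
  g <- compute_gaps(d, scenario_grid(12, 20, "physician_only"))
  expect_equal(g$gap, 0)
  expect_false(g$is_surplus)
  expect_equal(g$gap_pct, 0)
})

test_that("gap percentage uses supply as the base and flags zero supply", {
  expect_equal(gap_percentage(400, 400), 0)
  expect_equal(gap_percentage(800, 400), 100)
  expect_equal(gap_percentage(200, 400), -50)
  expect_equal(gap_percentage(1000, 400), 150) # above 100: need > double capacity
  expect_true(is.na(gap_percentage(100, 0)))
})

test_that("aggregation sums member gaps and counts surpluses", {
  d <- toy_dataset()
  scen <- scenario_grid(12, 20, "team")
  g <- compute_gaps(d, scen)
  s <- summarize_gaps(g, d)
  glob <- s[s$income_group == "GLOBAL", ]
  expect_equal(glob$cumulative_gap, sum(g$gap))
  expect_equal(glob$cumulative_gap_lo, sum(g$gap_lo))
  expect_equal(glob$cumulative_gap_hi, sum(g$gap_hi))
  expect_equal(glob$n_surplus, sum(g$gap < 0))
  # group rows partition the global row exactly
  groups <- s[s$income_group != "GLOBAL", ]
  expect_equal(sum(groups$cumulative_gap), glob$cumulative_gap)
  expect_equal(sum(groups$n_countries), glob$n_countries)
  # singleton group: mean defined, sd absent
  lic <- s[s$income_group == "LIC", ]
  expect_equal(lic$mean_prevalence, 37.5)
  expect_true(is.na(lic$sd_prevalence))
  # group descriptives are unweighted country means on the percent scale
  expect_equal(glob$mean_prevalence, 100 * mean(d$prevalence))
  expect_equal(glob$sd_prevalence, 100 * sd(d$prevalence))
  expect_equal(glob$mean_density_physician, mean(d$density_physician))
})

test_that("two-country aggregate reproduces the hand sum", {
  g <- tibble::tibble(
    iso3 = c("AAA", "BBB"),
    income_group = factor(c("LIC", "LIC"), levels = c("LIC", "LMIC", "UMIC", "HIC")),
    scenario = "v12_c20_team", visits_per_year = 12, patients_per_day = 20,
    care_model = factor("team", levels = c("physician_only", "nonphysician_only", "team")),
    demand = c(10e6, 1e6), demand_lo = c(9e6, 0.5e6), demand_hi = c(11e6, 1.5e6),
    supply = c(5e6, 3e6),
    gap = c(5e6, -2e6), gap_lo = c(4e6, -2.5e6), gap_hi = c(6e6, -1.5e6),
    gap_pct = c(100, -200 / 3), is_surplus = c(FALSE, TRUE)
  )
  d <- toy_dataset()[1:2, ]
  d$iso3 <- c("AAA", "BBB"); d$income_group <- factor("LIC", levels = levels(d$income_group))
  s <- summarize_gaps(g, d)
  lic <- s[s$income_group == "LIC", ]
  expect_equal(lic$cumulative_gap, 3e6)
  expect_equal(lic$n_surplus, 1)
  expect_equal(lic$n_countries, 2)
  # gaps referencing unknown countries are refused
  g_bad <- g; g_bad$iso3[2] <- "ZZZ"
  expect_error(summarize_gaps(g_bad, d), class = "htngap_consistency_error")
})

test_that("surplus counting is strict and guards its preconditions", {
  base <- tibble::tibble(
    iso3 = c("AAA", "BBB", "CCC"), scenario = "v1_c20_team",
    gap = c(10, 0, -7)
  )
  expect_equal(count_surplus_countries(base), 1) # zero gap is balanced, not surplus
  expect_equal(count_surplus_countries(dplyr::mutate(base, gap = abs(gap))), 0)
  expect_error(count_surplus_countries(base[0, ]), class = "htngap_validation_error")
  expect_error(count_surplus_countries(dplyr::bind_rows(base, base[1, ])),
               class = "htngap_consistency_error")
  two_cells <- base; two_cells$scenario[1] <- "v12_c20_team"
  expect_error(count_surplus_countries(two_cells), class = "htngap_consistency_error")
})

test_that("surplus count matches a constructed membership", {
  # build countries where surplus membership is known by construction:
  # density 120 gives supply = demand at 12 visits & prevalence 0.4 (see
  # balanced-country test); above it surplus, below it deficit
  n <- 12
  surplus_idx <- c(2, 5, 6, 11)
  d <- tibble::tibble(
    iso3 = sprintf("C%02d", seq_len(n)), name = sprintf("C%02d", seq_len(n)),
    population_total = 1e6, population_eligible = 1e6,
    income_group = factor(rep("UMIC", n), levels = c("LIC", "LMIC", "UMIC", "HIC")),
    density_physician = ifelse(seq_len(n) %in% surplus_idx, 150, 90),
    density_nurse = NA_real_, density_pharmacist = NA_real_, density_chw = NA_real_,
    prevalence = 0.4, prevalence_lo = 0.4, prevalence_hi = 0.4
  )
  g <- compute_gaps(d, scenario_grid(12, 20, "physician_only"))
  expect_equal(count_surplus_countries(g), length(surplus_idx))
  expect_setequal(g$iso3[g$is_surplus], sprintf("C%02d", surplus_idx))
})

test_that("extreme ranking finds the largest deficit and surplus with tie rules", {
  g <- tibble::tibble(iso3 = c("AAA", "BBB", "CCC"), scenario = "s",
                      gap = c(10, 3, -7))
  ex <- rank_extremes(g)
  expect_equal(ex$largest_deficit$iso3, "AAA")
  expect_equal(ex$largest_deficit$gap, 10)
  expect_equal(ex$largest_surplus$iso3, "CCC")
  expect_equal(ex$largest_surplus$gap, -7)

  all_pos <- dplyr::mutate(g, gap = abs(gap))
  expect_null(rank_extremes(all_pos)$largest_surplus)

  tied <- tibble::tibble(iso3 = c("BBB", "AAA"), scenario = "s", gap = c(10, 10))
  expect_equal(rank_extremes(tied)$largest_deficit$iso3, "AAA")

  expect_error(rank_extremes(g[0, ]), class = "htngap_validation_error")
})

test_that("gap is monotone in demand drivers and capacity drivers", {
  d <- generate_dataset(small_config(seed = 7))
  grid <- scenario_grid()
  g <- compute_gaps(d, grid)

  by_country_model <- split(g, list(g$iso3, g$care_model, g$patients_per_day))
  for (blk in by_country_model) {
    blk <- blk[order(blk$visits_per_year), ]
    expect_true(all(diff(blk$gap) > 0)) # strict: every country has patients > 0
  }
  # more throughput, less gap
  wide <- tidyr::pivot_wider(g[c("iso3", "visits_per_year", "care_model",
                                 "patients_per_day", "gap")],
                             names_from = "patients_per_day", values_from = "gap")
  expect_true(all(wide$`20` <= wide$`10`))
  # raising any density cannot raise the gap
  denser <- dplyr::mutate(d, density_physician = density_physician * 2,
                          density_nurse = density_nurse * 1.5)
  g2 <- compute_gaps(denser, grid)
  expect_true(all(g2$gap <= g$gap))
})

test_that("team-based care never widens the gap relative to either single model", {
  d <- generate_dataset(small_config(seed = 13))
  g <- compute_gaps(d, scenario_grid())
  wide <- tidyr::pivot_wider(g[c("iso3", "visits_per_year", "patients_per_day",
                                 "care_model", "gap")],
                             names_from = "care_model", values_from = "gap")
  expect_true(all(wide$team <= wide$physician_only))
  expect_true(all(wide$team <= wide$nonphysician_only))
})

test_that("interval ordering holds for every result and aggregate", {
  d <- generate_dataset(small_config(seed = 31))
  g <- compute_gaps(d, scenario_grid())
  expect_true(all(g$gap_lo <= g$gap & g$gap <= g$gap_hi))
  expect_true(all(g$demand_lo <= g$demand & g$demand <= g$demand_hi))
  s <- summarize_gaps(g, d)
  expect_true(all(s$cumulative_gap_lo <= s$cumulative_gap &
                    s$cumulative_gap <= s$cumulative_gap_hi))
})
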