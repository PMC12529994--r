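test_that("income classification follows the GNI thresholds, boundaries inclusive", {
  expect_equal(as.character(classify_income(1085)), "LIC")
  expect_equal(as.character(classify_income(1086)), "LMIC")
  expect_equal(as.character(classify_income(4255)), "LMIC")
  expect_equal(as.character(classify_income(4256)), "UMIC")
  expect_equal(as.character(classify_income(13845)), "UMIC")
  expect_equal(as.character(classify_income(c(13846, 50000))), c("HIC", "HIC"))
  expect_error(classify_income(0), class = "rlang_error")
  expect_error(classify_income(-5), class = "rlang_error")
  expect_error(income_thresholds(lic_max = 5000, lmic_max = 4255))
})

test_that("income classification is monotone in GNI", {
  set.seed(11)
  gni <- sort(exp(runif(400, log(100), log(2e5))))
  groups <- as.integer(classify_income(gni))
  expect_true(all(diff(groups) >= 0))
  # custom thresholds shift the boundaries but keep monotonicity
  thr <- income_thresholds(500, 2000, 9000)
  expect_true(all(diff(as.integer(classify_income(gni, thr))) >= 0))
  expect_equal(as.character(classify_income(500, thr)), "LIC")
  expect_equal(as.character(classify_income(501, thr)), "LMIC")
})

test_that("density reader handles long layout and picks the latest year", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "country,code,year,value",
    "India,IND,2019,7.3",
    "India,IND,2021,",
    "Nepal,NPL,2015,2.0",
    "Nepal,NPL,2018,2.5",
    "Ghost,GHO,2019,",
    "Ghost,GHO,2020,"
  ), f)
  out <- read_density_table(f)
  expect_equal(out$iso3, c("IND", "NPL"))
  expect_equal(out$density[out$iso3 == "IND"], 7.3)
  expect_equal(out$year[out$iso3 == "IND"], 2019L)
  expect_equal(out$density[out$iso3 == "NPL"], 2.5)
  expect_equal(out$year[out$iso3 == "NPL"], 2018L)
  expect_false("GHO" %in% out$iso3) # no value in any year
})

test_that("density reader handles wide World Bank layout", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "Country Name,Country Code,2018,2020",
    "India,IND,7.0,7.3",
    "Nepal,NPL,2.0,"
  ), f)
  out <- read_density_table(f)
  expect_equal(out$density[out$iso3 == "IND"], 7.3)
  expect_equal(out$year[out$iso3 == "IND"], 2020L)
  expect_equal(out$density[out$iso3 == "NPL"], 2.0)
  expect_equal(out$year[out$iso3 == "NPL"], 2018L)
})

test_that("density reader rejects negative values and unreadable files", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("code,year,value", "IND,2019,-1"), f)
  expect_error(read_density_table(f), "IND", class = "htngap_validation_error")
  expect_error(read_density_table(file.path(tempdir(), "nope.csv")),
               class = "htngap_input_error")
})

test_that("prevalence reader normalises percent and proportion scales", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "code,prevalence,lower,upper",
    "NPL,37.5,30.9,44.1",
    "XXX,0.375,0.309,0.441"
  ), f)
  out <- read_prevalence_table(f)
  expect_equal(out$prevalence[out$iso3 == "NPL"], 0.375)
  expect_equal(out$prevalence_lo[out$iso3 == "NPL"], 0.309)
  expect_equal(out$prevalence_hi[out$iso3 == "NPL"], 0.441)
  # already-proportion row passes through unchanged
  expect_equal(unlist(out[out$iso3 == "XXX", c("prevalence", "prevalence_lo", "prevalence_hi")],
                      use.names = FALSE),
               c(0.375, 0.309, 0.441))
})

test_that("prevalence reader rejects malformed intervals and impossible values", {
  f1 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("code,prevalence,lower,upper", "AAA,30,35,40"), f1)
  expect_error(read_prevalence_table(f1), class = "htngap_validation_error")

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("code,prevalence,lower,upper", "AAA,120,100,140"), f2)
  expect_error(read_prevalence_table(f2), class = "htngap_validation_error")
})

test_that("dataset assembly applies the physician-density inclusion rule", {
  dens <- list(
    physician = tibble::tibble(iso3 = c("AAA", "BBB"), density = c(5, 10), year = 2021L),
    nurse = tibble::tibble(iso3 = c("AAA", "BBB", "CCC"), density = c(20, 30, 40), year = 2021L),
    chw = tibble::tibble(iso3 = "AAA", density = 2, year = 2021L)
  )
  prev <- tibble::tibble(iso3 = c("AAA", "BBB", "CCC"),
                         prevalence = c(0.3, 0.4, 0.35),
                         prevalence_lo = c(0.25, 0.35, 0.3),
                         prevalence_hi = c(0.35, 0.45, 0.4))
  pop <- tibble::tibble(iso3 = c("AAA", "BBB", "CCC"),
                        population_total = c(1e6, 2e6, 3e6))
  inc <- tibble::tibble(iso3 = c("AAA", "BBB", "CCC"),
                        gni_per_capita = c(800, 5000, 60000))

  msgs <- capture_messages(
    d <- assemble_dataset(dens, prev, pop, inc, adult_fraction = 0.5)
  )
  expect_true(any(grepl("CCC", msgs))) # dropped country is logged with a reason
  expect_equal(nrow(d), 2)
  expect_setequal(d$iso3, c("AAA", "BBB"))
  expect_equal(d$population_eligible, d$population_total * 0.5)
  expect_equal(as.character(d$income_group), c("LIC", "UMIC"))
  # optional density attached where present, missing otherwise
  expect_equal(chw_coverage(d), 1)
  expect_true(is.na(d$density_chw[d$iso3 == "BBB"]))
  expect_true(is.na(d$density_pharmacist[d$iso3 == "AAA"]))
})

test_that("assembly rejects duplicates and empty results", {
  dens <- list(physician = tibble::tibble(iso3 = c("AAA", "AAA"), density = c(5, 6), year = 2021L))
  prev <- tibble::tibble(iso3 = "AAA", prevalence = 0.3,
                         prevalence_lo = 0.25, prevalence_hi = 0.35)
  pop <- tibble::tibble(iso3 = "AAA", population_total = 1e6)
  inc <- tibble::tibble(iso3 = "AAA", income_group = "LIC")
  expect_error(assemble_dataset(dens, prev, pop, inc, quiet = TRUE),
               class = "htngap_validation_error")

  dens$physician <- tibble::tibble(iso3 = "ZZZ", density = 5, year = 2021L)
  expect_error(suppressMessages(assemble_dataset(dens, prev, pop, inc, quiet = TRUE)),
               class = "htngap_assembly_error")
})

test_that("canonical CSV round-trips a dataset exactly", {
  d <- generate_dataset(generator_config(seed = 3))
  f <- withr::local_tempfile(fileext = ".csv")
  write_dataset(d, f)
  back <- read_dataset(f)
  expect_equal(back, d)
  # missing optional densities survive as missing, not as zero
  expect_equal(which(is.na(back$density_chw)), which(is.na(d$density_chw)))
})

test_that("dataset validation catches each invariant violation", {
  d <- toy_dataset()
  expect_silent(validate_dataset(d))

  bad <- d; bad$iso3[2] <- "AAA"
  expect_error(validate_dataset(bad), "duplicate", class = "htngap_validation_error")

  bad <- d; bad$population_eligible[1] <- bad$population_total[1] * 2
  expect_error(validate_dataset(bad), class = "htngap_validation_error")

  bad <- d; bad$density_physician[3] <- NA
  expect_error(validate_dataset(bad), "physician", class = "htngap_validation_error")

  bad <- d; bad$prevalence_lo[1] <- 0.5 # above the point estimate
  expect_error(validate_dataset(bad), class = "htngap_validation_error")

  bad <- d; bad$density_nurse[1] <- -2
  expect_error(validate_dataset(bad), class = "htngap_validation_error")
})
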