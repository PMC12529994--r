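#' World Bank income-classification thresholds
#'
#' Gross national income (GNI) per capita cut points, in current US$, that
#' separate the four World Bank income groups. Defaults are the 2023 fiscal
#' year thresholds: low income at or below $1085, lower-middle at or below
#' $4255, upper-middle at or below $13845, and high income above that.
#'
#' The published ranges quote the same dollar value at the top of one band
#' and the bottom of the next; here each band is upper-inclusive, so every
#' GNI value maps to exactly one group.
#'
#' @param lic_max upper bound (inclusive) for low-income countries, US$
#' @param lmic_max upper bound (inclusive) for lower-middle-income countries
#' @param umic_max upper bound (inclusive) for upper-middle-income countries
#'
#' @return A named list of class `income_thresholds`.
#' @examples
#' income_thresholds()
#' classify_income(c(1085, 1086, 13845, 13846))
#' @export
income_thresholds <- function(lic_max = 1085, lmic_max = 4255, umic_max = 13845) {
  if (!(lic_max < lmic_max && lmic_max < umic_max)) {
    abort("income thresholds must satisfy lic_max < lmic_max < umic_max")
  }
  structure(
    list(lic_max = lic_max, lmic_max = lmic_max, umic_max = umic_max),
    class = "income_thresholds"
  )
}

#' Classify countries into World Bank income groups
#'
#' Total, monotone step function of GNI per capita: raising a country's GNI
#' never moves it to a lower income group.
#'
#' @param gni_per_capita numeric vector of GNI per capita, US$; must be > 0
#' @param thresholds an [income_thresholds()] object
#'
#' @return factor with levels `LIC < LMIC < UMIC < HIC`, same length as input
#' @examples
#' classify_income(c(800, 3000, 10000, 50000))
#' @export
classify_income <- function(gni_per_capita, thresholds = income_thresholds()) {
  stopifnot(inherits(thresholds, "income_thresholds"))
  if (any(!is.finite(gni_per_capita) | gni_per_capita <= 0)) {
    abort("gni_per_capita must be positive and finite")
  }
  cut(
    gni_per_capita,
    breaks = c(0, thresholds$lic_max, thresholds$lmic_max, thresholds$umic_max, Inf),
    labels = income_levels(),
    right = TRUE
  )
}
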