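# Internal helpers shared across modules.

#' Draw from a normal distribution truncated at zero
#'
#' Inverse-CDF sampler: a uniform draw is mapped through the normal quantile
#' function restricted to the mass above zero. Exact (no rejection loop), so
#' one draw consumes exactly one uniform variate — which keeps generated
#' datasets reproducible for a given seed regardless of parameter values.
#'
#' @param n number of draws
#' @param mean,sd parameters of the untruncated normal; `sd >= 0`
#' @return numeric vector of `n` strictly positive draws (or `mean` repeated
#'   when `sd == 0`)
#' @keywords internal
#' @noRd
rtruncnorm0 <- function(n, mean, sd) {
  mean <- rep_len(mean, n)
  sd <- rep_len(sd, n)
  stopifnot(all(sd >= 0))
  u <- runif(n)
  degenerate <- sd == 0
  p0 <- pnorm(0, mean = mean, sd = pmax(sd, .Machine$double.eps))
  out <- qnorm(p0 + u * (1 - p0), mean = mean, sd = pmax(sd, .Machine$double.eps))
  out[degenerate] <- pmax(mean[degenerate], 0)
  out
}

# Synthetic 3-letter country codes: AAA, AAB, ... deterministic in index.
synthetic_iso3 <- function(n) {
  stopifnot(n >= 1, n <= 26^3)
  idx <- seq_len(n) - 1L
  paste0(
    LETTERS[idx %/% 676L + 1L],
    LETTERS[(idx %/% 26L) %% 26L + 1L],
    LETTERS[idx %% 26L + 1L]
  )
}

# Income-group labels in ascending order of wealth; used for factor levels
# throughout so tables sort LIC -> HIC.
income_levels <- function() c("LIC", "LMIC", "UMIC", "HIC")

care_model_levels <- function() c("physician_only", "nonphysician_only", "team")

# Timestamped logging to stderr; level gating handled by the caller.
log_msg <- function(level, ...) {
  message(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), "[", level, "] ", ...)
}
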