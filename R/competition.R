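## Per-gastruloid competition readouts: reference-normalised counts, growth
## curves with doubling times, washout dilution arithmetic, and seeding
## stoichiometry.

#' Normalise per-gastruloid focal counts to a reference condition
#'
#' Each gastruloid's focal-population count (or intensity proxy) is divided
#' by the summary (default: arithmetic mean) of the focal value across
#' reference-condition gastruloids at the same time point. The mean of the
#' normalised values in a condition at a time point is the competition
#' effect-size ratio of that condition.
#'
#' @param counts long-format count table (`gastruloid_id`, `condition`,
#'   `time_h`, `population`, `count`).
#' @param focal_population population whose growth is read out.
#' @param reference_condition condition label serving as the denominator.
#' @param stat reference summary function (default [mean()]).
#' @return data frame of focal rows with `reference_value` and `normalized`
#'   appended.
#' @export
normalize_to_reference <- function(counts, focal_population,
                                   reference_condition, stat = mean) {
  d <- as.data.frame(counts)
  d <- d[d$population == focal_population, , drop = FALSE]
  check_that(nrow(d) > 0, "no rows for the focal population")
  ref <- d[d$condition == reference_condition, , drop = FALSE]
  check_that(nrow(ref) > 0,
             sprintf("reference condition '%s' not present",
                     reference_condition))
  refval <- tapply(ref$count, ref$time_h, stat)
  miss <- setdiff(unique(d$time_h), as.numeric(names(refval)))
  check_that(length(miss) == 0,
             paste("reference condition missing at time(s):",
                   paste(miss, collapse = ", ")))
  d$reference_value <- as.numeric(refval[as.character(d$time_h)])
  d$normalized <- d$count / d$reference_value
  d
}

#' Growth curves normalised to seeding numbers, with doubling time
#'
#' Computes `N_t / N_0` per gastruloid and time point, and estimates the
#' exponential-phase doubling time by a pooled log-linear fit of counts on
#' time over a stated window.
#'
#' @param counts long-format count table; seeding numbers are taken from
#'   `N0` or from the table's `seeding` attribute.
#' @param population population to follow.
#' @param N0 seeding count; default from `attr(counts, "seeding")`.
#' @param window time window (h) for the doubling-time fit; reported with
#'   the estimate.
#' @return list: `curve` (per gastruloid/time `ratio` column appended),
#'   `doubling_time` (h), `rate` (per h), `window`.
#' @export
growth_curve <- function(counts, population, N0 = NULL, window = c(0, 48)) {
  d <- as.data.frame(counts)
  d <- d[d$population == population, , drop = FALSE]
  check_that(nrow(d) > 0, "no rows for this population")
  if (is.null(N0)) N0 <- attr(counts, "seeding")[[population]]
  check_that(!is.null(N0) && N0 > 0, "seeding number N0 must be positive")
  d$ratio <- d$count / N0
  w <- d$time_h >= window[1] & d$time_h <= window[2] & d$count > 0
  fit <- stats::lm(log(count) ~ time_h, data = d[w, , drop = FALSE])
  rate <- unname(stats::coef(fit)[2])
  list(curve = d, doubling_time = log(2) / rate, rate = rate,
       window = window)
}

#' Residual drug concentration after serial medium exchanges
#'
#' Assuming complete mixing before each removal, `n` sequential exchanges of
#' `exchange_volume` out of `well_volume` dilute an initial concentration
#' `c0` to `c0 * ((well_volume - exchange_volume) / well_volume)^n`.
#'
#' @param c0 initial concentration (nM).
#' @param well_volume total well volume (µl).
#' @param exchange_volume volume replaced per exchange (µl), strictly
#'   between 0 and `well_volume`.
#' @param n_exchanges number of exchanges (>= 0).
#' @return residual concentration (nM).
#' @export
washout_concentration <- function(c0, well_volume, exchange_volume,
                                  n_exchanges) {
  check_that(c0 >= 0, "c0 must be nonnegative")
  check_that(exchange_volume > 0 && exchange_volume < well_volume,
             "need 0 < exchange_volume < well_volume")
  check_that(n_exchanges >= 0 && n_exchanges == round(n_exchanges),
             "n_exchanges must be a nonnegative integer")
  c0 * ((well_volume - exchange_volume) / well_volume)^n_exchanges
}

#' Seeding stoichiometry as per-population percentages
#'
#' @param seeded named vector of seeded cell counts per population.
#' @param digits decimals for half-up rounding; `NULL` for unrounded.
#' @return named vector of percentages.
#' @export
stoichiometry_fraction <- function(seeded, digits = 1) {
  total <- sum(seeded)
  check_that(total > 0, "total seeded count must be positive")
  pct <- 100 * seeded / total
  if (!is.null(digits)) pct <- round_half_up(pct, digits)
  pct
}
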