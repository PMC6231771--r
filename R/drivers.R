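# Environmental drivers of spring phenology: degree-day forcing, chilling
# hours, photoperiod, preseason temperature, forcing-fulfilment date.

# Check that (year, doy) rows form one unbroken daily chain.
.check_contiguous_days <- function(year, doy) {
  if (length(year) < 2) return(TRUE)
  ok_same <- year[-1] == year[-length(year)] & doy[-1] == doy[-length(doy)] + 1
  ok_roll <- year[-1] == year[-length(year)] + 1 & doy[-1] == 1 &
    doy[-length(doy)] >= 365
  all(ok_same | ok_roll)
}

#' Degree-day sum over a window
#'
#' Accumulated forcing between two days of one year: the sum over days of
#' `max(T_d - base, 0)` with base temperature 5 degC by default. Negative
#' increments are clamped at zero, the standard growing-degree-day
#' convention. Sub-daily series are first collapsed to daily means.
#'
#' @param climate A `climate_series` (any resolution).
#' @param year Calendar year of the window.
#' @param t_end_doy Last day-of-year included (e.g. the leaf-out date).
#' @param t0_doy First day included; 1 (1 January) by default.
#' @param base Base temperature, degC.
#' @return Degree-days (numeric scalar, >= 0).
#' @export
degree_days <- function(climate, year, t_end_doy, t0_doy = 1, base = 5) {
  if (t_end_doy < t0_doy) .stop_invalid("t_end_doy must be >= t0_doy")
  d <- .as_daily(climate)
  w <- d[d$year == year & d$doy >= t0_doy & d$doy <= t_end_doy, , drop = FALSE]
  n_expect <- t_end_doy - t0_doy + 1
  if (nrow(w) != n_expect || anyDuplicated(w$doy))
    .stop_missing_data(sprintf(
      "daily series has gaps in year %d, days %d..%d", year, t0_doy, t_end_doy))
  sum(pmax(w$temp - base, 0))
}

#' Chilling hours between two dates
#'
#' Sum of hours with mean temperature between `t_low` and `t_high`
#' (0-5 degC), accumulated from 1 November of the preceding year until the
#' event by default. Each time step whose temperature falls in the band
#' contributes its step length in hours (a 6-h step contributes 6, a daily
#' step 24).
#'
#' @param climate A `climate_series`; step size must divide 24 h.
#' @param t_end_year,t_end_doy End of accumulation (inclusive).
#' @param t0_year,t0_doy Start of accumulation; defaults to DOY 305
#'   (1 November of a 365-day year) of the preceding year.
#' @param t_low,t_high Chilling temperature band, degC.
#' @return Chilling hours (numeric scalar).
#' @export
chilling_hours <- function(climate, t_end_year, t_end_doy,
                           t0_year = t_end_year - 1, t0_doy = 305,
                           t_low = 0, t_high = 5) {
  step <- attr(climate, "step_hours") %||% 24
  if (step > 24) .stop_invalid("time step exceeds 24 h")
  key <- climate$year * 1000L + climate$doy
  k0 <- t0_year * 1000L + t0_doy
  k1 <- t_end_year * 1000L + t_end_doy
  sel <- key >= k0 & key <= k1
  w <- climate[sel, , drop = FALSE]
  if (nrow(w) == 0) .stop_missing_data("no climate data in chilling window")
  dkey <- sort(unique(w$year * 1000L + w$doy))
  yy <- dkey %/% 1000L; dd <- dkey %% 1000L
  if (yy[1] != t0_year || dd[1] != t0_doy ||
      yy[length(yy)] != t_end_year || dd[length(dd)] != t_end_doy ||
      !.check_contiguous_days(yy, dd))
    .stop_missing_data("climate series has gaps in the chilling window")
  sum(step * (w$temp >= t_low & w$temp <= t_high))
}

#' Day length from latitude and day-of-year
#'
#' Photoperiod (hours from sunrise to sunset, sun 0.8333 degrees below the
#' horizon) via the CBM model: solar orbit angle
#' `theta = 0.2163108 + 2 * atan(0.9671396 * tan(0.0086 * (DOY - 186)))`,
#' declination angle `phi = asin(0.39795 * cos(theta))`, and
#' `DL = 24 - (24/pi) * acos((sin(0.8333 pi/180) + sin(L pi/180) sin(phi)) /
#' (cos(L pi/180) cos(phi)))`. The inverse-cosine argument is clamped to
#' \[-1, 1\] so polar day and polar night return 24 and 0 h.
#'
#' @param lat Latitude in degrees, in \[-90, 90\]. Vectorized.
#' @param doy Day-of-year, in \[1, 366\]. Vectorized.
#' @return Day length in hours, in \[0, 24\].
#' @export
day_length <- function(lat, doy) {
  if (any(!is.finite(lat)) || any(lat < -90 | lat > 90))
    .stop_invalid("latitude must lie in [-90, 90]")
  if (any(!is.finite(doy)) || any(doy < 1 | doy > 366))
    .stop_invalid("doy must lie in [1, 366]")
  theta <- 0.2163108 + 2 * atan(0.9671396 * tan(0.0086 * (doy - 186)))
  phi <- asin(0.39795 * cos(theta))
  a <- (sin(0.8333 * pi / 180) + sin(lat * pi / 180) * sin(phi)) /
    (cos(lat * pi / 180) * cos(phi))
  24 - (24 / pi) * acos(pmin(pmax(a, -1), 1))
}

#' Mean temperature over the preseason window
#'
#' Arithmetic mean of daily temperature over the `window` days immediately
#' preceding `mean_event_doy` (the event day itself is excluded). The window
#' may extend into the preceding year.
#'
#' @param climate A `climate_series`.
#' @param year Year of the event.
#' @param mean_event_doy Day-of-year of the (mean) phenological event.
#' @param window Window length in days (60 by default).
#' @return Mean temperature, degC.
#' @export
preseason_temperature <- function(climate, year, mean_event_doy, window = 60) {
  if (window < 1) .stop_invalid("window must be >= 1")
  d <- .as_daily(climate)
  doy0 <- round(mean_event_doy)
  idx <- which(d$year == year & d$doy == doy0)
  if (length(idx) != 1)
    .stop_missing_data(sprintf("event day %d of year %d not in series", doy0, year))
  if (idx - window < 1)
    .stop_missing_data("preseason window extends before series start")
  w <- d[(idx - window):(idx - 1), , drop = FALSE]
  if (!.check_contiguous_days(c(w$year, year), c(w$doy, doy0)))
    .stop_missing_data("daily series has gaps in the preseason window")
  mean(w$temp)
}

#' Day-of-year on which a forcing requirement is fulfilled
#'
#' Smallest day `t` such that the degree-day sum accumulated from `t0_doy`
#' (1 January by default) through `t` reaches `requirement`. Returns
#' `NA_integer_` if the requirement is never reached within the year
#' (an explicit missing flag, not an error).
#'
#' @param climate A `climate_series`.
#' @param year Year searched.
#' @param requirement Forcing requirement in degree-days, > 0.
#' @param t0_doy Start of accumulation.
#' @param base Base temperature, degC.
#' @return Day-of-year (integer) or `NA_integer_`.
#' @export
forcing_fulfilment_doy <- function(climate, year, requirement,
                                   t0_doy = 1, base = 5) {
  if (!is.finite(requirement) || requirement <= 0)
    .stop_invalid("requirement must be > 0")
  d <- .as_daily(climate)
  w <- d[d$year == year & d$doy >= t0_doy, , drop = FALSE]
  if (nrow(w) == 0) .stop_missing_data(sprintf("year %d not in series", year))
  if (!.check_contiguous_days(w$year, w$doy) || w$doy[1] != t0_doy)
    .stop_missing_data("daily series has gaps")
  cum <- cumsum(pmax(w$temp - base, 0))
  i <- match(TRUE, cum >= requirement)
  if (is.na(i)) NA_integer_ else as.integer(w$doy[i])
}
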