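#' @useDynLib phenosync, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif sd median coef lm anova t.test qt pt var
#'   complete.cases quantile cor setNames model.matrix reformulate
#' @importFrom utils read.csv write.csv combn modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

.stop_invalid <- function(msg) {
  stop(structure(class = c("phenosync_invalid_parameter", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
.stop_missing_data <- function(msg) {
  stop(structure(class = c("phenosync_missing_data", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
.stop_degenerate <- function(msg) {
  stop(structure(class = c("phenosync_degenerate", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Parameters of the synthetic temperature generator
#'
#' Defines a multi-year temperature series as a seasonal cycle plus a linear
#' warming trend, independent year-level offsets and AR(1) day-to-day noise.
#' Sub-daily resolutions add a sinusoidal diurnal cycle around the daily mean
#' (needed for chilling-hour computation).
#'
#' Defaults emulate a Central European lowland station: annual mean 9 degC,
#' seasonal half-amplitude 9.5 degC (January about -0.5 degC, July about
#' 18.5 degC), interannual offsets with SD 1.2 degC, AR(1) noise with
#' stationary SD 2.5 degC and autocorrelation 0.7, diurnal half-range 4 degC.
#'
#' @param annual_mean Annual mean temperature, degC.
#' @param seasonal_amplitude Half-amplitude of the seasonal cosine, degC.
#' @param warming_trend Linear trend, degC per year.
#' @param year_offsets_sd SD of independent year-level offsets, degC.
#' @param noise_sd Stationary SD of the AR(1) daily noise, degC.
#' @param noise_autocorr Lag-1 autocorrelation of the daily noise, in [0, 1).
#' @param resolution One of `"daily"`, `"6-hourly"`, `"hourly"`.
#' @param n_years Number of years (365-day years), at least 1.
#' @param diurnal_amplitude Half-range of the diurnal cycle, degC
#'   (sub-daily resolutions only; the daily mean is preserved exactly).
#' @param seed Integer seed; the series is a pure function of the parameters.
#' @param year_offsets Optional explicit numeric vector of year offsets
#'   (length `n_years`) overriding the random draws, e.g. to impose a known
#'   warming contrast between years.
#' @param start_year First calendar year label.
#' @return A list of class `climate_params`.
#' @export
climate_params <- function(annual_mean = 9, seasonal_amplitude = 9.5,
                           warming_trend = 0, year_offsets_sd = 1.2,
                           noise_sd = 2.5, noise_autocorr = 0.7,
                           resolution = c("daily", "6-hourly", "hourly"),
                           n_years = 20, diurnal_amplitude = 4,
                           seed = 1L, year_offsets = NULL,
                           start_year = 2001L) {
  resolution <- match.arg(resolution)
  if (!is.numeric(n_years) || n_years < 1)
    .stop_invalid("n_years must be >= 1")
  if (noise_autocorr < 0 || noise_autocorr >= 1)
    .stop_invalid("noise_autocorr must lie in [0, 1)")
  if (!is.null(year_offsets) && length(year_offsets) != n_years)
    .stop_invalid("year_offsets must have length n_years")
  structure(list(annual_mean = annual_mean,
                 seasonal_amplitude = seasonal_amplitude,
                 warming_trend = warming_trend,
                 year_offsets_sd = year_offsets_sd,
                 noise_sd = noise_sd, noise_autocorr = noise_autocorr,
                 resolution = resolution, n_years = as.integer(n_years),
                 diurnal_amplitude = diurnal_amplitude,
                 seed = as.integer(seed), year_offsets = year_offsets,
                 start_year = as.integer(start_year)),
            class = "climate_params")
}

#' Generate a synthetic temperature series
#'
#' Daily mean temperature on day-of-year d of year y is
#' `annual_mean + warming_trend * (y - 1) + offset_y +
#'  seasonal_amplitude * cos(2 * pi * (d - 200) / 365) + AR(1) noise`,
#' so mid-July (DOY 200) is the warmest point of the cycle. The AR(1) noise
#' runs continuously across year boundaries with stationary SD `noise_sd`.
#' Sub-daily steps add `diurnal_amplitude * cos(2 * pi * (hour - 15) / 24)`,
#' which averages to zero over any full day at the supported step sizes.
#'
#' @param params A [climate_params()] object.
#' @return A `climate_series`: data frame with columns `year`, `doy`, `hour`,
#'   `temp`, and attributes `step_hours` and `site_id`. Years have 365 days.
#' @export
generate_temperature_series <- function(params) {
  if (!inherits(params, "climate_params"))
    params <- do.call(climate_params, as.list(params))
  set.seed(params$seed)
  ny <- params$n_years
  offs <- params$year_offsets %||% rnorm(ny, 0, params$year_offsets_sd)
  doy <- seq_len(365)
  seas <- params$seasonal_amplitude * cos(2 * pi * (doy - 200) / 365)
  base <- rep(params$annual_mean + params$warming_trend * (seq_len(ny) - 1) + offs,
              each = 365) + rep(seas, ny)
  n <- 365L * ny
  if (params$noise_sd > 0) {
    rho <- params$noise_autocorr
    innov <- c(rnorm(1, 0, params$noise_sd),
               rnorm(n - 1, 0, params$noise_sd * sqrt(1 - rho^2)))
    noise <- as.numeric(stats::filter(innov, rho, method = "recursive"))
  } else noise <- numeric(n)
  daily <- base + noise
  years <- params$start_year + rep(seq_len(ny) - 1L, each = 365L)
  doys <- rep(doy, ny)
  step <- switch(params$resolution, daily = 24, `6-hourly` = 6, hourly = 1)
  if (step == 24) {
    out <- data.frame(year = years, doy = doys, hour = 0, temp = daily)
  } else {
    hours <- seq(0, 23.999, by = step)
    diur <- params$diurnal_amplitude * cos(2 * pi * (hours - 15) / 24)
    out <- data.frame(year = rep(years, each = length(hours)),
                      doy = rep(doys, each = length(hours)),
                      hour = rep(hours, n),
                      temp = rep(daily, each = length(hours)) + rep(diur, n))
  }
  structure(out, step_hours = step, site_id = "synthetic",
            class = c("climate_series", "data.frame"))
}

#' @export
print.climate_series <- function(x, ...) {
  cat(sprintf("<climate_series> %d rows, step %g h, years %d-%d\n",
              nrow(x), attr(x, "step_hours"), min(x$year), max(x$year)))
  invisible(x)
}

# Collapse a climate series to daily means (year, doy, temp), sorted.
# Fast no-op for daily input; sub-daily steps average exactly to the
# daily mean because each day carries a full set of steps.
.as_daily <- function(climate) {
  if (inherits(climate, "daily_climate")) return(climate)
  stopifnot(all(c("year", "doy", "temp") %in% names(climate)))
  step <- attr(climate, "step_hours") %||% 24
  if (step == 24) {
    d <- data.frame(year = climate$year, doy = climate$doy, temp = climate$temp)
  } else {
    g <- climate$year * 1000L + climate$doy
    m <- rowsum(climate$temp, g) / rowsum(rep(1, nrow(climate)), g)
    key <- as.integer(rownames(m))
    d <- data.frame(year = key %/% 1000L, doy = key %% 1000L, temp = m[, 1])
  }
  d <- d[order(d$year, d$doy), , drop = FALSE]
  rownames(d) <- NULL
  class(d) <- c("daily_climate", "data.frame")
  d
}

#' Write / read a climate series as CSV
#'
#' Columns `site_id,timestamp_iso8601,temp_c`. Daily series use dates,
#' sub-daily series UTC datetimes. Reading recovers `year`, `doy`, `hour`.
#'
#' @param climate A `climate_series`.
#' @param path File path.
#' @return `read_climate_csv` returns a `climate_series`.
#' @export
write_climate_csv <- function(climate, path) {
  step <- attr(climate, "step_hours") %||% 24
  d0 <- as.Date(sprintf("%d-01-01", climate$year)) + (climate$doy - 1)
  ts <- if (step == 24) format(d0, "%Y-%m-%d") else
    sprintf("%sT%02d:00:00Z", format(d0, "%Y-%m-%d"), as.integer(climate$hour))
  write.csv(data.frame(site_id = attr(climate, "site_id") %||% "site",
                       timestamp_iso8601 = ts, temp_c = climate$temp),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_climate_csv
#' @export
read_climate_csv <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  sub_daily <- grepl("T", x$timestamp_iso8601[1], fixed = TRUE)
  if (sub_daily) {
    tt <- as.POSIXlt(x$timestamp_iso8601, tz = "UTC",
                     format = "%Y-%m-%dT%H:%M:%SZ")
    hour <- tt$hour
  } else {
    tt <- as.POSIXlt(as.Date(x$timestamp_iso8601))
    hour <- rep(0, nrow(x))
  }
  out <- data.frame(year = tt$year + 1900L, doy = tt$yday + 1L,
                    hour = hour, temp = x$temp_c)
  hrs <- sort(unique(hour))
  step <- if (length(hrs) > 1) min(diff(hrs)) else 24
  structure(out, step_hours = step, site_id = x$site_id[1],
            class = c("climate_series", "data.frame"))
}
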