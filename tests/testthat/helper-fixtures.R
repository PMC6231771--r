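# Fixture builders shared across the suite. All synthetic, built in code.

# Climate with one temperature value per day, from a constant or a
# function of DOY (recycled over years).
make_climate <- function(temp, years = 2001, step_hours = 24, days = 365) {
  doy <- seq_len(days)
  tday <- if (is.function(temp)) temp(doy) else rep(temp, days)
  if (step_hours == 24) {
    out <- data.frame(year = rep(years, each = days),
                      doy = rep(doy, length(years)), hour = 0,
                      temp = rep(tday, length(years)))
  } else {
    hours <- seq(0, 23.999, by = step_hours)
    out <- data.frame(
      year = rep(years, each = days * length(hours)),
      doy = rep(rep(doy, each = length(hours)), length(years)),
      hour = rep(hours, days * length(years)),
      temp = rep(rep(tday, each = length(hours)), length(years)))
  }
  structure(out, step_hours = step_hours, site_id = "fixture",
            class = c("climate_series", "data.frame"))
}

# Minimal record table; vectors are recycled to equal length.
make_records <- function(series_id, year, doy, lat = 48.2, lon = 11.3,
                         alt_m = 500, species = "Fagus sylvatica",
                         phase = "leafout_BBCH11") {
  data.frame(series_id = series_id, species = species, phase = phase,
             lat = lat, lon = lon, alt_m = alt_m, year = year, doy = doy)
}

# A panel built directly from a dates matrix (individuals x years).
make_panel <- function(dates, altitudes = rep(500, nrow(dates)),
                       lat = 48.2, lon = 11.3) {
  structure(list(pixel = c(lat_index = floor(lat), lon_index = floor(lon)),
                 species = "Fagus sylvatica", phase = "leafout_BBCH11",
                 individuals = rownames(dates),
                 years = as.integer(colnames(dates)), dates = dates,
                 altitudes = stats::setNames(altitudes, rownames(dates)),
                 lat = lat, lon = lon),
            class = "pixel_panel")
}
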