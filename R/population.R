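# Synthetic populations: within-population heterogeneity in forcing,
# day-length and chilling requirements, and event-date simulation.

#' Specification of a synthetic plant population
#'
#' Individual traits are drawn from normal distributions: a base forcing
#' requirement (degree-days needed under 16-h days and reference chilling),
#' a day-length sensitivity (degree-days per hour of day length; negative
#' values mean the requirement grows when days are short) and a chilling
#' sensitivity (degree-days per chilling hour; negative values mean the
#' requirement grows when chilling is low).
#'
#' Default trait scales are anchored on twig-experiment observations for
#' European beech: base requirement around 100 degree-days from 1 January (placing leaf-out in late April under the default climate); day-length
#' slopes spanning roughly 0 (insensitive) to -27 DD/h (an individual
#' needing more than twice the warming under 8-h than under 16-h days);
#' chilling slopes small and homogeneous.
#'
#' @param n_individuals Number of individuals (>= 1).
#' @param forcing_req_mean,forcing_req_sd Base forcing requirement, DD.
#' @param daylength_sens_mean,daylength_sens_sd Day-length sensitivity, DD/h.
#' @param chilling_sens_mean,chilling_sens_sd Chilling sensitivity,
#'   DD per chilling hour.
#' @param latitude,longitude Population location, degrees. Individuals are
#'   jittered within +/- 0.4 degrees so they share the 1-degree pixel of the
#'   centre coordinate (for half-degree centres).
#' @param altitude_mean,altitude_sd Altitude distribution, m.
#' @param species,phase Labels for emitted records.
#' @param seed Integer seed for trait draws.
#' @return A list of class `population_spec`.
#' @export
population_spec <- function(n_individuals = 12,
                            forcing_req_mean = 100, forcing_req_sd = 20,
                            daylength_sens_mean = -14, daylength_sens_sd = 9,
                            chilling_sens_mean = -0.10, chilling_sens_sd = 0.02,
                            latitude = 48.5, longitude = 11.5,
                            altitude_mean = 500, altitude_sd = 50,
                            species = "Fagus sylvatica",
                            phase = "leafout_BBCH11", seed = 1L) {
  if (n_individuals < 1) .stop_invalid("n_individuals must be >= 1")
  sds <- c(forcing_req_sd, daylength_sens_sd, chilling_sens_sd, altitude_sd)
  if (any(sds < 0)) .stop_invalid("SD fields must be >= 0")
  if (forcing_req_mean <= 0) .stop_invalid("forcing_req_mean must be > 0")
  structure(as.list(environment()), class = "population_spec")
}

#' Draw individual traits for a population
#'
#' @param pop A [population_spec()].
#' @return Data frame: `id`, `forcing_req` (floored at 20 DD),
#'   `daylength_sens`, `chilling_sens`, `lat`, `lon`, `alt_m`.
#' @export
draw_individual_traits <- function(pop) {
  set.seed(pop$seed)
  n <- pop$n_individuals
  data.frame(
    id = sprintf("ind%03d", seq_len(n)),
    forcing_req = pmax(rnorm(n, pop$forcing_req_mean, pop$forcing_req_sd), 20),
    daylength_sens = rnorm(n, pop$daylength_sens_mean, pop$daylength_sens_sd),
    chilling_sens = rnorm(n, pop$chilling_sens_mean, pop$chilling_sens_sd),
    lat = pop$latitude + runif(n, -0.4, 0.4),
    lon = pop$longitude + runif(n, -0.4, 0.4),
    alt_m = round(rnorm(n, pop$altitude_mean, pop$altitude_sd)))
}

# Cumulative chilling hours per day of `year`, accumulated from
# (year-1, chill_start_doy); element d = chilling through day d.
.chill_prefix <- function(climate, year, n_days, chill_start_doy = 305,
                          t_low = 0, t_high = 5) {
  step <- attr(climate, "step_hours") %||% 24
  key <- climate$year * 1000L + climate$doy
  sel <- (key >= (year - 1) * 1000L + chill_start_doy) &
    (key <= year * 1000L + n_days)
  w <- climate[sel, , drop = FALSE]
  contrib <- step * (w$temp >= t_low & w$temp <= t_high)
  daily <- rowsum(contrib, w$year * 1000L + w$doy)
  dkey <- as.integer(rownames(daily))
  cum <- cumsum(daily[, 1])
  this_year <- dkey %/% 1000L == year
  days <- dkey[this_year] %% 1000L
  if (!all(seq_len(n_days) %in% days))
    .stop_missing_data("climate series has gaps in the chilling window")
  out <- numeric(n_days)
  out[days] <- cum[this_year]
  out
}

#' Simulate leaf-out events for a population
#'
#' For each individual i and year, the event is the first day t on which
#' degree-days accumulated from 1 January reach the individual's effective
#' requirement
#' `F_eff_i(t) = forcing_req_i + daylength_sens_i * (DL(t) - 16) +
#'  chilling_sens_i * (Ch(t) - ch_ref)`, floored at `f_min`. `DL` is the
#' photoperiod at the population latitude, `Ch(t)` the chilling hours
#' accumulated since 1 November of the preceding year, and `ch_ref` a
#' reference chilling level at which the base requirement applies.
#'
#' Years whose preceding 1 November is not covered by the climate series are
#' skipped when any chilling sensitivity is non-zero (the chilling driver is
#' not computable there); with all chilling sensitivities zero every climate
#' year is simulated. An individual-year whose requirement is never reached
#' by `search_end_doy` is kept as a row with `doy = NA` (explicit missing
#' flag, not a dropped record).
#'
#' @param pop A [population_spec()], or a traits data frame from
#'   [draw_individual_traits()] plus `species`/`phase`/`latitude` attributes
#'   taken from `pop`.
#' @param climate A `climate_series`.
#' @param ch_ref Reference chilling, hours.
#' @param f_min Floor of the effective requirement, degree-days.
#' @param dl_ref Reference day length, hours.
#' @param search_end_doy Last day searched for the event.
#' @param base Forcing base temperature, degC.
#' @param chill_start_doy Chilling accumulation start (DOY of previous year).
#' @return Data frame of phenological records: `series_id`, `species`,
#'   `phase`, `lat`, `lon`, `alt_m`, `year`, `doy` (NA = event not reached).
#' @export
simulate_events <- function(pop, climate, ch_ref = 1800, f_min = 10,
                            dl_ref = 16, search_end_doy = 240, base = 5,
                            chill_start_doy = 305) {
  traits <- draw_individual_traits(pop)
  daily <- .as_daily(climate)
  years <- sort(unique(daily$year))
  use_chill <- any(traits$chilling_sens != 0)
  dl <- day_length(pop$latitude, seq_len(search_end_doy))
  res <- vector("list", length(years))
  for (k in seq_along(years)) {
    y <- years[k]
    have_prev <- any(daily$year == y - 1 & daily$doy >= chill_start_doy)
    if (use_chill && !have_prev) next
    w <- daily[daily$year == y & daily$doy <= search_end_doy, , drop = FALSE]
    if (nrow(w) < search_end_doy || !.check_contiguous_days(w$year, w$doy) ||
        w$doy[1] != 1) next
    cum_dd <- cumsum(pmax(w$temp - base, 0))
    ch <- if (use_chill)
      .chill_prefix(climate, y, search_end_doy, chill_start_doy) else
        rep(ch_ref, search_end_doy)
    n <- nrow(traits)
    f_eff <- matrix(traits$forcing_req, n, search_end_doy) +
      outer(traits$daylength_sens, dl - dl_ref) +
      outer(traits$chilling_sens, ch - ch_ref)
    f_eff <- pmax(f_eff, f_min)
    hit <- sweep(f_eff, 2, cum_dd, function(f, cd) cd >= f)
    event <- apply(hit, 1, function(z) {
      i <- match(TRUE, z)
      if (is.na(i)) NA_integer_ else as.integer(i)
    })
    res[[k]] <- data.frame(series_id = traits$id, species = pop$species,
                           phase = pop$phase, lat = traits$lat,
                           lon = traits$lon, alt_m = traits$alt_m,
                           year = y, doy = event)
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(series_id = character(), species = character(),
                      phase = character(), lat = numeric(), lon = numeric(),
                      alt_m = numeric(), year = integer(), doy = integer())
  rownames(out) <- NULL
  out
}

#' Write / read phenological records as CSV
#'
#' The record dialect has columns
#' `series_id,species,phase,lat,lon,alt_m,year,doy` with 1-based DOY.
#' `emit_records` drops rows whose event was never reached (`doy` NA);
#' the write/read pair round-trips losslessly.
#'
#' @param records Data frame of phenological records.
#' @param path File path.
#' @return `read_pheno_csv` returns the records data frame.
#' @export
emit_records <- function(records, path) {
  write.csv(records[!is.na(records$doy), , drop = FALSE], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname emit_records
#' @export
read_pheno_csv <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("series_id", "species", "phase", "lat", "lon", "alt_m", "year", "doy")
  if (!all(need %in% names(x)))
    .stop_invalid(paste("record CSV must have columns:",
                        paste(need, collapse = ",")))
  if (any(x$doy < 1 | x$doy > 366)) .stop_invalid("doy must lie in [1, 366]")
  x[need]
}
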