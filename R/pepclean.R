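# Cleaning and pixelization of PEP725-style phenological record tables.
# Filter order is fixed: series-SD -> MAD outliers -> pixel assignment ->
# panel construction -> altitude filter -> coverage filter.

#' Drop erratic observation series
#'
#' Removes every series whose across-year sample standard deviation of the
#' event day-of-year exceeds `threshold` (strictly; SD equal to the
#' threshold is kept). Series with fewer than two years are kept here (their
#' SD is undefined); they cannot survive the shared-years panel requirement
#' anyway.
#'
#' @param records Phenological records (see [read_pheno_csv()]).
#' @param threshold SD threshold in days.
#' @return Filtered records.
#' @export
filter_series_sd <- function(records, threshold = 25) {
  s <- tapply(records$doy, records$series_id, function(x)
    if (length(x) < 2) 0 else sd(x))
  keep <- names(s)[s <= threshold]
  records[records$series_id %in% keep, , drop = FALSE]
}

#' Drop outlying observations within each series
#'
#' Removes observations deviating from the series median by more than
#' `k` times the median absolute deviation (MAD, unscaled: the median of
#' absolute deviations, without the 1.4826 normal-consistency factor).
#' Degenerate case: when MAD is 0, any observation off the median is
#' removed.
#'
#' @param records Phenological records.
#' @param k Multiplier of the MAD.
#' @return Filtered records.
#' @export
filter_mad_outliers <- function(records, k = 3) {
  keep <- unlist(lapply(split(seq_len(nrow(records)), records$series_id),
                        function(idx) {
    x <- records$doy[idx]
    m <- median(x)
    mad0 <- median(abs(x - m))
    idx[abs(x - m) <= k * mad0]
  }), use.names = FALSE)
  out <- records[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign 1-degree pixels
#'
#' Pixel indices are the floor of latitude and longitude; a coordinate on
#' the degree boundary belongs to the pixel it indexes.
#'
#' @param records Phenological records with `lat`/`lon`.
#' @return Records with added integer columns `lat_index`, `lon_index`.
#' @export
assign_pixels <- function(records) {
  records$lat_index <- as.integer(floor(records$lat))
  records$lon_index <- as.integer(floor(records$lon))
  records
}

# Largest subset of series sharing >= min_shared common years.
# Exhaustive over subset sizes (largest first) for small groups; greedy
# removal of the most year-set-limiting series otherwise.
.select_series <- function(years_list, min_individuals, min_shared,
                           exhaustive_max = 12) {
  ids <- names(years_list)
  n <- length(ids)
  if (n < min_individuals) return(NULL)
  n_common <- function(sel) length(Reduce(intersect, years_list[sel]))
  if (n_common(ids) >= min_shared) return(ids)
  if (n <= exhaustive_max) {
    for (size in seq(n - 1, min_individuals)) {
      subs <- combn(ids, size, simplify = FALSE)
      hits <- vapply(subs, n_common, integer(1))
      if (any(hits >= min_shared)) return(subs[[which(hits >= min_shared)[1]]])
    }
    return(NULL)
  }
  sel <- ids
  while (length(sel) > min_individuals) {
    gains <- vapply(seq_along(sel),
                    function(i) n_common(sel[-i]), integer(1))
    best <- which.max(gains)                      # ties: first id dropped
    sel <- sel[-best]
    if (n_common(sel) >= min_shared) return(sel)
  }
  NULL
}

#' Build per-pixel observation panels
#'
#' For each (pixel, species, phase) group, retains the largest set of series
#' that share at least `min_shared_years` common observation years, and
#' arranges their dates as an individuals-by-years matrix with explicit
#' missing values. Groups that cannot supply `min_individuals` such series
#' yield no panel.
#'
#' @param records Records with pixel indices (see [assign_pixels()]).
#' @param min_individuals Minimum individuals per panel.
#' @param min_shared_years Minimum number of years shared by all retained
#'   individuals.
#' @return List of `pixel_panel` objects. Each holds `pixel`, `species`,
#'   `phase`, `individuals`, `years` (union of the retained series' years),
#'   `dates` (matrix, NA = missing), `altitudes`, and the mean `lat`/`lon`.
#' @export
build_panels <- function(records, min_individuals = 3, min_shared_years = 15) {
  if (is.null(records$lat_index)) records <- assign_pixels(records)
  grp <- interaction(records$lat_index, records$lon_index,
                     records$species, records$phase, drop = TRUE)
  panels <- lapply(split(records, grp), function(g) {
    yl <- lapply(split(g$year, g$series_id), unique)
    sel <- .select_series(yl, min_individuals, min_shared_years)
    if (is.null(sel)) return(NULL)
    g <- g[g$series_id %in% sel, , drop = FALSE]
    inds <- sort(unique(g$series_id))
    yrs <- sort(unique(g$year))
    m <- matrix(NA_real_, length(inds), length(yrs),
                dimnames = list(inds, yrs))
    m[cbind(match(g$series_id, inds), match(g$year, yrs))] <- g$doy
    alts <- vapply(split(g$alt_m, g$series_id), function(a) mean(a), 0)
    structure(list(pixel = c(lat_index = g$lat_index[1],
                             lon_index = g$lon_index[1]),
                   species = g$species[1], phase = g$phase[1],
                   individuals = inds, years = yrs, dates = m,
                   altitudes = alts[inds],
                   lat = mean(g$lat), lon = mean(g$lon)),
              class = "pixel_panel")
  })
  unname(Filter(Negate(is.null), panels))
}

#' @export
print.pixel_panel <- function(x, ...) {
  cat(sprintf("<pixel_panel> (%d, %d) %s/%s: %d individuals x %d years\n",
              x$pixel[1], x$pixel[2], x$species, x$phase,
              length(x$individuals), length(x$years)))
  invisible(x)
}

#' Drop altitude outliers from a panel
#'
#' Single pass: individuals whose altitude deviates by more than `max_dev`
#' from the mean altitude of all panel individuals are removed (strict
#' inequality; a deviation equal to `max_dev` is kept).
#'
#' @param panel A `pixel_panel`.
#' @param max_dev Maximum altitude deviation, m.
#' @return The filtered panel.
#' @export
filter_altitude <- function(panel, max_dev = 200) {
  keep <- abs(panel$altitudes - mean(panel$altitudes)) <= max_dev
  panel$individuals <- panel$individuals[keep]
  panel$altitudes <- panel$altitudes[keep]
  panel$dates <- panel$dates[keep, , drop = FALSE]
  panel
}

#' Drop low-coverage years from a panel
#'
#' Removes years in which fewer than `min_coverage` of the panel's
#' individuals have an observation (a coverage of exactly `min_coverage`
#' is kept).
#'
#' @param panel A `pixel_panel`.
#' @param min_coverage Minimum fraction of observed individuals per year.
#' @return The filtered panel.
#' @export
filter_coverage <- function(panel, min_coverage = 0.90) {
  cov <- colMeans(!is.na(panel$dates))
  keep <- cov >= min_coverage
  panel$years <- panel$years[keep]
  panel$dates <- panel$dates[, keep, drop = FALSE]
  panel
}

#' Full cleaning chain from raw records to panels
#'
#' Applies, in fixed order: the series-SD filter, the MAD outlier filter,
#' pixel assignment, panel construction, the altitude filter and the
#' coverage filter, then drops panels that no longer meet the minimum
#' individual and shared-year requirements. Counts removed at each step are
#' returned as an auditable log.
#'
#' @param records Raw phenological records.
#' @param sd_threshold,mad_k,min_individuals,min_shared_years,max_alt_dev,min_coverage
#'   Filter parameters, see the individual filters.
#' @return List with `panels` (list of `pixel_panel`) and `log`
#'   (named integer vector of removal counts).
#' @export
pep_clean <- function(records, sd_threshold = 25, mad_k = 3,
                      min_individuals = 3, min_shared_years = 15,
                      max_alt_dev = 200, min_coverage = 0.90) {
  log <- c(records_in = nrow(records))
  r1 <- filter_series_sd(records, sd_threshold)
  log["removed_series_sd"] <- nrow(records) - nrow(r1)
  r2 <- filter_mad_outliers(r1, mad_k)
  log["removed_mad_outliers"] <- nrow(r1) - nrow(r2)
  r3 <- assign_pixels(r2)
  panels <- build_panels(r3, min_individuals, min_shared_years)
  log["panels_built"] <- length(panels)
  panels <- lapply(panels, function(p) {
    n0 <- length(p$individuals)
    p <- filter_altitude(p, max_alt_dev)
    attr(p, "removed_altitude") <- n0 - length(p$individuals)
    y0 <- length(p$years)
    p <- filter_coverage(p, min_coverage)
    attr(p, "removed_years_coverage") <- y0 - length(p$years)
    p
  })
  log["removed_altitude"] <- sum(vapply(panels, attr, 0L, "removed_altitude"))
  log["removed_years_coverage"] <-
    sum(vapply(panels, attr, 0L, "removed_years_coverage"))
  ok <- vapply(panels, function(p)
    length(p$individuals) >= min_individuals &&
      length(p$years) >= min_shared_years, TRUE)
  panels <- panels[ok]
  log["panels_out"] <- length(panels)
  list(panels = panels, log = log)
}
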