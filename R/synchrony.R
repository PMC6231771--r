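# Per-pixel synchrony statistics and their relation to preseason
# temperature, chilling and photoperiod.

#' Synchrony series for a cleaned panel
#'
#' For every retained panel year computes:
#' \itemize{
#'   \item `sd_doy` — leaf-out/flowering synchrony (LOS/FLS): the sample
#'     standard deviation (n-1 denominator) of event dates across the
#'     individuals observed that year (larger = less synchronous);
#'   \item `sd_dd` — LOS-DD/FLS-DD: the sample SD of the individuals'
#'     degree-day sums from 1 January to their own event date;
#'   \item `mean_doy` — mean event date;
#'   \item `preseason_temp` — mean temperature over the `window` days
#'     before the panel's long-term mean event date (one fixed window per
#'     pixel; set `per_year_window = TRUE` to centre the window on each
#'     year's own mean date instead);
#'   \item `mean_chilling` — mean over individuals of chilling hours from
#'     1 November of the preceding year to the individual's event
#'     (NA when the preceding autumn is not covered by the climate);
#'   \item `dl_at_forcing` — mean over individuals of the day length on the
#'     date when the individual's across-year mean forcing requirement is
#'     fulfilled in that year.
#' }
#' Years with fewer than two observed individuals are kept as rows flagged
#' by NA statistics.
#'
#' @param panel A `pixel_panel`.
#' @param climate A `climate_series` covering the panel years.
#' @param window Preseason window length, days.
#' @param per_year_window Use each year's own mean event date for the
#'   preseason window instead of the long-term pixel mean.
#' @param base Forcing base temperature, degC.
#' @param chill_start_doy Chilling accumulation start DOY (previous year).
#' @return Data frame of class `synchrony_series` with one row per year and
#'   attributes `pixel`, `species`, `phase`.
#' @export
compute_synchrony <- function(panel, climate, window = 60,
                              per_year_window = FALSE, base = 5,
                              chill_start_doy = 305) {
  daily <- .as_daily(climate)
  yrs <- panel$years
  dates <- panel$dates
  grand_mean_doy <- round(mean(dates, na.rm = TRUE))
  clim_years <- unique(daily$year)

  # per-year cumulative degree-days from 1 Jan
  cum_dd <- lapply(setNames(yrs, yrs), function(y) {
    w <- daily[daily$year == y, , drop = FALSE]
    if (nrow(w) == 0) return(NULL)
    cumsum(pmax(w$temp - base, 0))
  })

  # per-individual forcing requirement at its own event, then its
  # across-year mean
  dd_at_event <- matrix(NA_real_, nrow(dates), ncol(dates),
                        dimnames = dimnames(dates))
  for (j in seq_along(yrs)) {
    cd <- cum_dd[[as.character(yrs[j])]]
    if (is.null(cd)) next
    d <- dates[, j]
    ok <- !is.na(d)
    dd_at_event[ok, j] <- cd[d[ok]]
  }
  mean_req <- rowMeans(dd_at_event, na.rm = TRUE)

  rows <- lapply(seq_along(yrs), function(j) {
    y <- yrs[j]
    d <- dates[, j]
    obs <- which(!is.na(d))
    out <- data.frame(year = y, n_obs = length(obs), sd_doy = NA_real_,
                      sd_dd = NA_real_, mean_doy = NA_real_,
                      preseason_temp = NA_real_, mean_chilling = NA_real_,
                      dl_at_forcing = NA_real_)
    if (length(obs) < 2) return(out)
    out$sd_doy <- sd(d[obs])
    out$sd_dd <- sd(dd_at_event[obs, j])
    out$mean_doy <- mean(d[obs])
    ref_doy <- if (per_year_window) round(out$mean_doy) else grand_mean_doy
    out$preseason_temp <- tryCatch(
      preseason_temperature(climate, y, ref_doy, window),
      phenosync_missing_data = function(e) NA_real_)
    if ((y - 1) %in% clim_years) {
      ch <- tryCatch(
        .chill_prefix(climate, y, max(d[obs]), chill_start_doy),
        phenosync_missing_data = function(e) NULL)
      if (!is.null(ch)) out$mean_chilling <- mean(ch[d[obs]])
    }
    cd <- cum_dd[[as.character(y)]]
    if (!is.null(cd)) {
      dls <- vapply(obs, function(i) {
        if (!is.finite(mean_req[i]) || mean_req[i] <= 0) return(NA_real_)
        t <- match(TRUE, cd >= mean_req[i])
        if (is.na(t)) NA_real_ else day_length(panel$lat, t)
      }, 0)
      out$dl_at_forcing <- mean(dls, na.rm = TRUE)
    }
    out
  })
  out <- do.call(rbind, rows)
  structure(out, pixel = panel$pixel, species = panel$species,
            phase = panel$phase, lat = panel$lat,
            class = c("synchrony_series", "data.frame"))
}

#' Per-pixel linear regression of synchrony on a driver
#'
#' Ordinary least squares of a synchrony-series response on a predictor,
#' with the Pearson correlation and a two-sided p-value from the t
#' distribution with n - 2 degrees of freedom.
#'
#' @param series A `synchrony_series` (or plain data frame).
#' @param predictor Column name: `"preseason_temp"`, `"mean_chilling"` or
#'   `"dl_at_forcing"`.
#' @param response Column name: `"sd_doy"`, `"sd_dd"` or `"mean_doy"`.
#' @return List of class `pixel_regression`: `r`, `slope`, `intercept`,
#'   `p_value`, `n_years`.
#' @export
pixel_regression <- function(series, predictor = "preseason_temp",
                             response = "sd_doy") {
  x <- series[[predictor]]
  y <- series[[response]]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) .stop_invalid("need at least 3 complete years")
  if (sd(x) == 0 || sd(y) == 0)
    .stop_degenerate("zero-variance predictor or response")
  fit <- lm(y ~ x)
  n <- length(x)
  r <- cor(x, y)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  structure(list(r = r, slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 p_value = 2 * pt(-abs(tstat), n - 2), n_years = n,
                 predictor = predictor, response = response),
            class = "pixel_regression")
}

#' Summarize per-pixel correlations across pixels
#'
#' Mean correlation coefficient with a t-based 95 percent confidence
#' interval, a two-sided one-sample t-test of the mean against zero, and the
#' percentage of pixels whose correlation has the focal sign (and, of
#' those, is significant at `alpha`).
#'
#' @param regressions List of `pixel_regression` objects.
#' @param alpha Per-pixel significance level.
#' @param direction `"auto"` (sign of the mean r), `"positive"` or
#'   `"negative"`.
#' @return List of class `correlation_summary`: `mean_r`,
#'   `ci95_halfwidth`, `pct_focal_sign`, `pct_significant`, `t_statistic`,
#'   `p_value`, `n_pixels`, `direction`.
#' @export
summarize_correlations <- function(regressions, alpha = 0.05,
                                   direction = c("auto", "positive",
                                                 "negative")) {
  direction <- match.arg(direction)
  if (length(regressions) < 2) .stop_invalid("need at least 2 pixels")
  rs <- vapply(regressions, function(g) g$r, 0)
  ps <- vapply(regressions, function(g) g$p_value, 0)
  mean_r <- mean(rs)
  n <- length(rs)
  degenerate <- sd(rs) == 0
  if (degenerate) {
    warning("all correlation coefficients identical; t-test undefined")
    half <- 0; tstat <- NA_real_; pval <- NA_real_
  } else {
    tt <- t.test(rs)
    half <- unname(diff(tt$conf.int)) / 2
    tstat <- unname(tt$statistic)
    pval <- tt$p.value
  }
  if (direction == "auto")
    direction <- if (mean_r >= 0) "positive" else "negative"
  focal <- if (direction == "positive") rs > 0 else rs < 0
  structure(list(mean_r = mean_r, ci95_halfwidth = half,
                 pct_focal_sign = 100 * mean(focal),
                 pct_significant = 100 * mean(focal & ps < alpha),
                 t_statistic = tstat, p_value = pval, n_pixels = n,
                 direction = direction, degenerate = degenerate),
            class = "correlation_summary")
}

#' Cross-pixel distribution model of dates or synchrony
#'
#' Random-intercept regression of a synchrony-series response (mean event
#' date or synchrony SD) on preseason temperature across pixels, with pixel
#' as the random effect, fitted with the package's hierarchical Bayesian
#' sampler on the raw (unstandardized) scale. Posterior means are reported
#' as estimates with central 95 percent credible intervals. With a single
#' pixel the model collapses to OLS, with a warning.
#'
#' @param series_list List of `synchrony_series` (one per pixel).
#' @param response,predictor Column names, as in [pixel_regression()].
#' @param chains,iterations,burnin,seed MCMC settings, see [fit_hb_model()].
#' @return List of class `distribution_model`: `slope`, `slope_ci`,
#'   `intercept`, `var_pixel`, `sigma2`, `method`, and (for the Bayesian
#'   fit) the full `hb_posterior` as `posterior`.
#' @export
fit_distribution_model <- function(series_list, response = "sd_doy",
                                   predictor = "preseason_temp",
                                   chains = 3, iterations = 4000,
                                   burnin = 1000, seed = 1) {
  if (inherits(series_list, "synchrony_series")) series_list <- list(series_list)
  df <- do.call(rbind, lapply(seq_along(series_list), function(i) {
    s <- series_list[[i]]
    px <- attr(s, "pixel")
    data.frame(dependent = s[[response]], x = s[[predictor]],
               pixel = if (!is.null(px)) paste(px, collapse = "_") else
                 as.character(i))
  }))
  df <- df[complete.cases(df), , drop = FALSE]
  n_px <- length(unique(df$pixel))
  if (n_px < 2) {
    warning("single pixel: distribution model collapses to OLS")
    if (nrow(df) < 3) .stop_invalid("need at least 3 complete years")
    fit <- lm(dependent ~ x, data = df)
    ci <- stats::confint(fit)["x", ]
    return(structure(list(slope = unname(coef(fit)[2]),
                          slope_ci = unname(ci),
                          intercept = unname(coef(fit)[1]),
                          var_pixel = 0,
                          sigma2 = summary(fit)$sigma^2, method = "ols"),
                     class = "distribution_model"))
  }
  hb_data <- data.frame(dependent = df$dependent, preseason_temp = df$x,
                        pixel = df$pixel)
  fit <- fit_hb_model(hb_data, variant = "temperature", chains = chains,
                      iterations = iterations, burnin = burnin, seed = seed,
                      standardize = FALSE)
  s <- fit$summary
  structure(list(slope = s["beta_preseason_temp", "mean"],
                 slope_ci = unlist(s["beta_preseason_temp",
                                     c("q2.5", "q97.5")], use.names = FALSE),
                 intercept = s["alpha", "mean"],
                 var_pixel = s["var_pixel", "mean"],
                 sigma2 = s["sigma2", "mean"],
                 method = "hbayes", posterior = fit),
            class = "distribution_model")
}

#' Synchrony change between a cold and a warm preseason
#'
#' Predicts the within-pixel SD of event dates at two preseason
#' temperatures from a fitted distribution model and expresses the change
#' as a percentage and as the lengthening of the 95 percent leaf-out
#' window. Under the normal model of within-pixel dates, 95 percent of
#' individuals fall in a window of width 2 x 1.96 x SD, so the window
#' lengthens by `3.92 * (SD_warm - SD_cold)` days.
#'
#' @param model A `distribution_model` fitted on an SD response.
#' @param temp_cold,temp_warm Preseason temperatures, degC.
#' @return List: `sd_cold`, `sd_warm`, `pct_sd_increase`,
#'   `window_lengthening_days`.
#' @export
synchrony_change_metrics <- function(model, temp_cold, temp_warm) {
  sd_cold <- model$intercept + model$slope * temp_cold
  sd_warm <- model$intercept + model$slope * temp_warm
  synchrony_change_from_sd(sd_cold, sd_warm)
}

#' @rdname synchrony_change_metrics
#' @param sd_cold,sd_warm Within-pixel SD of dates (days) at the two
#'   temperatures.
#' @export
synchrony_change_from_sd <- function(sd_cold, sd_warm) {
  if (!is.finite(sd_cold) || sd_cold <= 0)
    .stop_degenerate("SD under the cold preseason must be > 0")
  list(sd_cold = sd_cold, sd_warm = sd_warm,
       pct_sd_increase = 100 * (sd_warm - sd_cold) / sd_cold,
       window_lengthening_days = 3.92 * (sd_warm - sd_cold))
}

#' Export a synchrony series as tidy CSV
#'
#' One row per pixel-year with the pixel, species and phase attributes as
#' leading columns.
#'
#' @param series A `synchrony_series`.
#' @param path File path.
#' @export
write_synchrony_csv <- function(series, path) {
  px <- attr(series, "pixel")
  out <- cbind(data.frame(lat_index = px[1], lon_index = px[2],
                          species = attr(series, "species"),
                          phase = attr(series, "phase")),
               as.data.frame(series))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
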