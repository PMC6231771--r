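# Twig-cutting experiment analytics: per-individual estimation of forcing,
# day-length and chilling requirements, ANOVA variance partitioning of
# leaf-out dates, and random-effects variance components.

#' Mean leaf-out date of the first k twigs
#'
#' Mean of the `k` earliest leaf-out dates among the replicates of one
#' individual-treatment cell. When fewer than `k` replicates leafed out the
#' mean is computed over the available ones and flagged (attribute
#' `incomplete`, plus a warning).
#'
#' @param dates Replicate leaf-out dates (numeric; NA = never leafed out).
#' @param k Number of earliest replicates averaged.
#' @return Mean date, with attributes `n_used` and `incomplete`.
#' @export
mean_leafout_first_k <- function(dates, k = 8) {
  x <- sort(dates[!is.na(dates)])
  if (length(x) == 0) .stop_missing_data("no replicate leafed out")
  incomplete <- length(x) < k
  if (incomplete)
    warning(sprintf("only %d of %d requested replicates leafed out",
                    length(x), k))
  n_used <- min(k, length(x))
  structure(mean(x[seq_len(n_used)]), n_used = n_used,
            incomplete = incomplete)
}

#' Day-length sensitivity of one individual
#'
#' OLS slope of the degree-days needed until leaf-out on the day-length
#' treatment (hours). More negative slopes indicate stronger day-length
#' sensitivity (less warming needed under long days).
#'
#' @param dd Degree-day sums until leaf-out, one per treatment level.
#' @param hours Day-length treatments, h (e.g. 8, 12, 16).
#' @return Slope in DD per hour.
#' @export
daylength_sensitivity <- function(dd, hours) {
  if (length(unique(hours)) < 2)
    .stop_invalid("need at least 2 day-length levels")
  unname(coef(lm(dd ~ hours))[2])
}

#' Chilling sensitivity of one individual
#'
#' OLS slope of the degree-days needed until leaf-out on the chilling hours
#' accumulated at twig collection (under constant 16-h days). More negative
#' slopes indicate stronger chilling sensitivity.
#'
#' @param dd Degree-day sums until leaf-out, one per collection.
#' @param chill_hours Accumulated chilling hours at each collection.
#' @return Slope in DD per chilling hour.
#' @export
chilling_sensitivity <- function(dd, chill_hours) {
  if (length(unique(chill_hours)) < 2)
    .stop_invalid("need at least 2 chilling levels")
  unname(coef(lm(dd ~ chill_hours))[2])
}

#' Forcing requirement of one individual
#'
#' The degree-day sum until leaf-out in the long-chilling (last collection)
#' x 16-h day-length cell, where chilling and day-length requirements are
#' assumed met and the remaining variation reflects forcing alone.
#'
#' @param twigs Twig observations of one individual: data frame with
#'   columns `collection`, `daylength_h`, `dd_at_leafout` (and optionally
#'   `leafout_date` for first-k selection).
#' @param collection The long-chilling collection label; defaults to the
#'   maximum of `collection` (interpreting larger = later = more chilling).
#' @param daylength_h Day-length treatment of the reference cell, h.
#' @param k Number of earliest replicates averaged within the cell.
#' @return Forcing requirement in degree-days.
#' @export
forcing_requirement <- function(twigs, collection = max(twigs$collection),
                                daylength_h = 16, k = 8) {
  cell <- twigs[twigs$collection == collection &
                  twigs$daylength_h == daylength_h, , drop = FALSE]
  cell <- cell[!is.na(cell$dd_at_leafout), , drop = FALSE]
  if (nrow(cell) == 0)
    .stop_missing_data("long-chilling / 16-h cell not observed")
  ord <- if (!is.null(cell$leafout_date)) order(cell$leafout_date) else
    order(cell$dd_at_leafout)
  mean(cell$dd_at_leafout[ord][seq_len(min(k, nrow(cell)))])
}

#' Estimate all three traits for every individual
#'
#' Per individual: the forcing requirement from the long-chilling x 16-h
#' cell, the day-length sensitivity across the 8/12/16-h treatments at the
#' last collection, and the chilling sensitivity across collections at
#' 16-h days. Cell values are means of the `k` earliest replicates.
#'
#' @param twigs Twig observation table: `individual_id`, `collection`,
#'   `daylength_h`, `replicate`, `leafout_date`, `dd_at_leafout`.
#' @param chill_at_collection Named numeric vector mapping collection
#'   labels to accumulated chilling hours at collection.
#' @param k Replicates averaged per cell.
#' @return Data frame: `individual_id`, `forcing_req`, `daylength_sens`,
#'   `chilling_sens`.
#' @export
twig_traits <- function(twigs, chill_at_collection, k = 8) {
  cell_mean <- function(d) {
    d <- d[!is.na(d$dd_at_leafout), , drop = FALSE]
    if (nrow(d) == 0) return(NA_real_)
    ord <- if (!is.null(d$leafout_date)) order(d$leafout_date) else
      order(d$dd_at_leafout)
    mean(d$dd_at_leafout[ord][seq_len(min(k, nrow(d)))])
  }
  last_coll <- names(chill_at_collection)[which.max(chill_at_collection)]
  out <- lapply(split(twigs, twigs$individual_id), function(ind) {
    dl_cells <- ind[ind$collection == last_coll, , drop = FALSE]
    dl_levels <- sort(unique(dl_cells$daylength_h))
    dl_dd <- vapply(dl_levels, function(h)
      cell_mean(dl_cells[dl_cells$daylength_h == h, ]), 0)
    ch_cells <- ind[ind$daylength_h == 16, , drop = FALSE]
    ch_levels <- sort(unique(ch_cells$collection))
    ch_dd <- vapply(ch_levels, function(cc)
      cell_mean(ch_cells[ch_cells$collection == cc, ]), 0)
    ch_hours <- chill_at_collection[as.character(ch_levels)]
    data.frame(individual_id = ind$individual_id[1],
               forcing_req = forcing_requirement(ind, last_coll, 16, k),
               daylength_sens = daylength_sensitivity(dl_dd, dl_levels),
               chilling_sens = chilling_sensitivity(ch_dd, ch_hours))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Partition leaf-out variation among the three cues
#'
#' For each chilling level, regresses the individuals' leaf-out dates on
#' their three trait estimates and expresses each cue's sequential (Type I)
#' sum of squares — in the fixed order forcing, day length, chilling by
#' default — as a percentage of the total SS including the residual.
#' Percentages sum to 100. With correlated traits the attribution depends
#' on the order; `order` can be permuted to probe this.
#'
#' @param leafout Data frame: `individual_id`, `chilling_level`,
#'   `leafout` (date or DOY).
#' @param traits Trait estimates from [twig_traits()].
#' @param order Character vector permuting
#'   `c("forcing", "daylength", "chilling")`.
#' @return Data frame, one row per chilling level: percentage columns
#'   `pct_forcing`, `pct_daylength`, `pct_chilling`, `pct_residual` and the
#'   per-cue p-values.
#' @export
partition_variance_anova <- function(leafout, traits,
                                     order = c("forcing", "daylength",
                                               "chilling")) {
  stopifnot(setequal(order, c("forcing", "daylength", "chilling")))
  d <- merge(leafout, traits, by = "individual_id")
  vars <- c(forcing = "forcing_req", daylength = "daylength_sens",
            chilling = "chilling_sens")[order]
  rows <- lapply(split(d, d$chilling_level), function(g) {
    form <- stats::reformulate(vars, response = "leafout")
    fit <- lm(form, data = g)
    if (any(is.na(coef(fit))))
      warning("collinear trait predictors; sequential attribution applies")
    a <- anova(fit)
    ss <- a[["Sum Sq"]]
    pct <- 100 * ss / sum(ss)
    names(pct) <- c(order, "residual")
    pv <- a[["Pr(>F)"]][seq_along(order)]
    names(pv) <- order
    data.frame(chilling_level = g$chilling_level[1],
               pct_forcing = pct[["forcing"]],
               pct_daylength = pct[["daylength"]],
               pct_chilling = pct[["chilling"]],
               pct_residual = pct[["residual"]],
               p_forcing = pv[["forcing"]],
               p_daylength = pv[["daylength"]],
               p_chilling = pv[["chilling"]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Variance components of leaf-out dates
#'
#' Decomposes the total variance of twig leaf-out dates into treatment
#' (chilling level), between-individual (individuals nested within
#' treatments) and within-individual (residual) components, reported as
#' percentages summing to 100.
#'
#' Methods: `"reml"` fits the random-effects-only model
#' `leafout ~ 1 + (1 | treatment) + (1 | treatment:individual)` by
#' restricted maximum likelihood (lme4); `"moments"` uses the balanced
#' expected-mean-squares equations from the nested ANOVA table, truncating
#' negative estimates at zero with a flag.
#'
#' @param twigs Data frame: `individual_id`, `treatment`, `leafout`.
#' @param method `"reml"` or `"moments"`.
#' @return List of class `variance_components`: `variances` and `pct`
#'   (named: treatment, individual, residual), `method`, `truncated`.
#' @export
variance_components <- function(twigs, method = c("reml", "moments")) {
  method <- match.arg(method)
  if (length(unique(twigs$treatment)) < 2 ||
      length(unique(twigs$individual_id)) < 2)
    .stop_invalid("need >= 2 treatments and >= 2 individuals")
  twigs$treatment <- factor(twigs$treatment)
  twigs$individual_id <- factor(twigs$individual_id)
  truncated <- FALSE
  if (method == "reml") {
    fit <- lme4::lmer(
      leafout ~ 1 + (1 | treatment) + (1 | treatment:individual_id),
      data = twigs,
      control = lme4::lmerControl(check.conv.singular = "ignore"))
    vc <- as.data.frame(lme4::VarCorr(fit))
    v <- setNames(vc$vcov, vc$grp)
    vars <- c(treatment = unname(v["treatment"]),
              individual = unname(v["treatment:individual_id"]),
              residual = unname(v["Residual"]))
  } else {
    a <- length(levels(twigs$treatment))
    cell <- table(twigs$treatment, twigs$individual_id)
    r <- unique(as.vector(cell))
    if (length(r) != 1)
      .stop_invalid("moments method requires a balanced design")
    b <- ncol(cell)
    fit <- lm(leafout ~ treatment + treatment:individual_id, data = twigs)
    an <- anova(fit)
    ms <- an[["Mean Sq"]]
    names(ms) <- rownames(an)
    ms_t <- ms[["treatment"]]
    ms_i <- ms[["treatment:individual_id"]]
    ms_e <- ms[["Residuals"]]
    v_i <- (ms_i - ms_e) / r
    v_t <- (ms_t - ms_i) / (b * r)
    if (v_i < 0 || v_t < 0) truncated <- TRUE
    vars <- c(treatment = max(v_t, 0), individual = max(v_i, 0),
              residual = ms_e)
  }
  structure(list(variances = vars, pct = 100 * vars / sum(vars),
                 method = method, truncated = truncated),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("<variance_components> (%s)%s\n", x$method,
              if (x$truncated) " [negative estimate truncated]" else ""))
  print(round(x$pct, 1))
  invisible(x)
}

#' Simulate a nested twig experiment
#'
#' Generates leaf-out dates `y = grand_mean + t_j + b_ij + e_ijk` with
#' treatment effects `t_j ~ N(0, var_treatment)`, individual-within-
#' treatment effects `b_ij ~ N(0, var_individual)` and replicate noise
#' `e_ijk ~ N(0, var_residual)` — the structure assumed by
#' [variance_components()]. Default dimensions follow the second beech
#' experiment: 11 individuals x 8 chilling treatments x 8 scored twigs.
#'
#' @param n_individuals,n_treatments,n_replicates Design dimensions.
#' @param var_individual,var_treatment,var_residual Planted variance
#'   components (days^2).
#' @param grand_mean Mean leaf-out date.
#' @param seed Integer seed.
#' @return Data frame: `individual_id`, `treatment`, `replicate`,
#'   `leafout`.
#' @export
simulate_twig_experiment <- function(n_individuals = 11, n_treatments = 8,
                                     n_replicates = 8,
                                     var_individual = 52,
                                     var_treatment = 33,
                                     var_residual = 15,
                                     grand_mean = 30, seed = 1) {
  set.seed(seed)
  tr <- rnorm(n_treatments, 0, sqrt(var_treatment))
  bi <- matrix(rnorm(n_treatments * n_individuals, 0, sqrt(var_individual)),
               n_treatments, n_individuals)
  idx <- expand.grid(replicate = seq_len(n_replicates),
                     individual = seq_len(n_individuals),
                     treatment = seq_len(n_treatments))
  data.frame(individual_id = sprintf("ind%02d", idx$individual),
             treatment = sprintf("T%02d", idx$treatment),
             replicate = idx$replicate,
             leafout = grand_mean + tr[idx$treatment] +
               bi[cbind(idx$treatment, idx$individual)] +
               rnorm(nrow(idx), 0, sqrt(var_residual)))
}

#' Simulate twig observations from planted traits
#'
#' Chamber-style observation table from the additive trait model: the
#' degree-days needed in cell (collection c, day length h) are
#' `forcing_req + daylength_sens * (h - 16) + chilling_sens *
#' (chill_c - max(chill))`, floored at `f_min`, plus replicate noise.
#' Leaf-out dates follow by dividing degree-days by the daily chamber
#' forcing rate (16 degC mean, base 5: 11 DD/day).
#'
#' @param traits Data frame with `individual_id` (or `id`), `forcing_req`,
#'   `daylength_sens`, `chilling_sens`.
#' @param chill_at_collection Named vector: collection label -> chilling
#'   hours.
#' @param daylengths Day-length treatments, h.
#' @param n_replicates Replicates per cell.
#' @param noise_sd Replicate noise on the DD scale.
#' @param forcing_rate Chamber forcing, DD per day.
#' @param f_min Floor of the cell requirement, DD.
#' @param seed Integer seed.
#' @return Twig observation table as used by [twig_traits()].
#' @export
simulate_twig_observations <- function(traits, chill_at_collection,
                                       daylengths = c(8, 12, 16),
                                       n_replicates = 10, noise_sd = 5,
                                       forcing_rate = 11, f_min = 10,
                                       seed = 1) {
  set.seed(seed)
  if (is.null(traits$individual_id)) traits$individual_id <- traits$id
  colls <- names(chill_at_collection)
  ch_max <- max(chill_at_collection)
  grid <- expand.grid(replicate = seq_len(n_replicates),
                      daylength_h = daylengths, collection = colls,
                      individual_id = traits$individual_id,
                      stringsAsFactors = FALSE)
  i <- match(grid$individual_id, traits$individual_id)
  dd_true <- pmax(traits$forcing_req[i] +
                    traits$daylength_sens[i] * (grid$daylength_h - 16) +
                    traits$chilling_sens[i] *
                    (chill_at_collection[grid$collection] - ch_max), f_min)
  dd <- pmax(dd_true + rnorm(nrow(grid), 0, noise_sd), 1)
  data.frame(individual_id = grid$individual_id,
             collection = grid$collection,
             daylength_h = grid$daylength_h, replicate = grid$replicate,
             leafout_date = dd / forcing_rate, dd_at_leafout = dd)
}
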