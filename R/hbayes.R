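# Hierarchical Bayesian regression of synchrony on environmental drivers
# with species and pixel random intercepts.

#' Two-SD standardization
#'
#' Centers a vector and divides by twice its sample standard deviation, so
#' the result has mean 0 and SD 0.5. This puts continuous predictors on a
#' scale comparable to binary ones and allows direct effect-size
#' comparison across coefficients.
#'
#' @param x Numeric vector with positive SD.
#' @return The standardized vector, with attributes `center` and `scale`
#'   (the 2-SD divisor).
#' @export
standardize_2sd <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) .stop_degenerate("constant vector")
  structure((x - mean(x)) / (2 * s), center = mean(x), scale = 2 * s)
}

#' Fit the hierarchical synchrony regression
#'
#' Normal regression of a synchrony measure on either preseason temperature
#' (`variant = "temperature"`) or day length and chilling jointly
#' (`variant = "daylength_chilling"`), with random intercepts for species
#' and for pixel where at least two levels are present (otherwise the
#' corresponding random effect is dropped with a warning). Priors follow
#' the model definition: N(0, 1000) on the intercept and slopes and
#' Uniform(0, 100) on the variances of the random intercepts (applied to
#' the variance, not the SD); the residual variance carries the same
#' Uniform(0, 100) prior. Sampling is by a blocked Gibbs sampler (see
#' the package vignette); convergence is assessed with the Gelman-Rubin
#' statistic across chains, and any parameter with Rhat > 1.1 triggers a
#' warning and `converged = FALSE`.
#'
#' @param data Data frame with columns `dependent`, the predictors required
#'   by the variant (`preseason_temp`, or `daylength` and `chilling`), and
#'   optionally `species` and `pixel` grouping columns.
#' @param variant `"temperature"` or `"daylength_chilling"`.
#' @param chains Number of parallel chains (>= 2 for diagnostics).
#' @param iterations Total iterations per chain.
#' @param burnin Iterations discarded from the start of each chain.
#' @param seed Integer seed; chain c uses `seed + c`.
#' @param standardize Standardize dependent and predictors by 2 SD before
#'   fitting (the convention for effect-size comparison); set `FALSE` to
#'   fit on the raw scale.
#' @param prior_beta_var Prior variance of intercept and slopes.
#' @param var_upper Upper bound of the uniform variance priors.
#' @return An `hb_posterior`: list with `draws` (per-chain matrices of
#'   post-burn-in draws), `summary` (mean, sd, central 95 percent credible
#'   interval and Rhat per parameter), `converged`, and bookkeeping fields.
#' @export
fit_hb_model <- function(data, variant = c("temperature",
                                           "daylength_chilling"),
                         chains = 3, iterations = 4000, burnin = 1000,
                         seed = 1, standardize = TRUE,
                         prior_beta_var = 1000, var_upper = 100) {
  variant <- match.arg(variant)
  preds <- switch(variant, temperature = "preseason_temp",
                  daylength_chilling = c("daylength", "chilling"))
  need <- c("dependent", preds)
  if (!all(need %in% names(data)))
    .stop_invalid(paste("data must contain columns:",
                        paste(need, collapse = ", ")))
  if (burnin >= iterations) .stop_invalid("burnin must be < iterations")
  keep <- complete.cases(data[need])
  data <- data[keep, , drop = FALSE]
  y <- data$dependent
  X <- cbind(alpha = rep(1, nrow(data)))
  for (p in preds) {
    v <- data[[p]]
    if (standardize) v <- standardize_2sd(v)
    X <- cbind(X, as.numeric(v))
    colnames(X)[ncol(X)] <- paste0("beta_", p)
  }
  if (standardize && nrow(data) > 0) y <- as.numeric(standardize_2sd(y))

  grp <- function(name) {
    if (is.null(data[[name]])) return(NULL)
    f <- factor(data[[name]])
    if (nlevels(f) < 2) {
      warning(sprintf("fewer than 2 %s levels: random effect dropped", name))
      return(NULL)
    }
    f
  }
  sp <- grp("species"); px <- grp("pixel")
  Z <- function(f, prefix) {
    if (is.null(f)) return(NULL)
    m <- model.matrix(~ f - 1)
    colnames(m) <- paste0(prefix, levels(f))
    m
  }
  W <- do.call(cbind, Filter(Negate(is.null),
                             list(X, Z(sp, "species_"), Z(px, "pixel_"))))
  p <- ncol(X); q_sp <- if (is.null(sp)) 0L else nlevels(sp)
  q_px <- if (is.null(px)) 0L else nlevels(px)

  draws <- vector("list", chains)
  for (ch in seq_len(chains)) {
    set.seed(seed + ch)
    d <- hb_gibbs_chain(y, W, p, q_sp, q_px, iterations,
                        prior_beta_var, var_upper)
    colnames(d) <- c(colnames(W), "sigma2", "var_species", "var_pixel")
    draws[[ch]] <- d[(burnin + 1):iterations, , drop = FALSE]
  }
  main <- c(colnames(X), "sigma2",
            if (q_sp > 0) "var_species", if (q_px > 0) "var_pixel")
  summ <- do.call(rbind, lapply(main, function(par) {
    v <- unlist(lapply(draws, function(d) d[, par]))
    rhat <- if (chains >= 2)
      suppressWarnings(gelman_rubin(sapply(draws, function(d) d[, par])))
    else NA_real_
    data.frame(mean = mean(v), sd = sd(v),
               q2.5 = unname(quantile(v, 0.025)),
               q97.5 = unname(quantile(v, 0.975)), rhat = rhat)
  }))
  rownames(summ) <- main
  converged <- chains < 2 || all(is.na(summ$rhat) | summ$rhat <= 1.1)
  if (!converged)
    warning("possible non-convergence: Gelman-Rubin Rhat > 1.1 for ",
            paste(main[!is.na(summ$rhat) & summ$rhat > 1.1], collapse = ", "))
  structure(list(draws = draws, summary = summ, converged = converged,
                 variant = variant, chains = chains, iterations = iterations,
                 burnin = burnin, standardize = standardize,
                 n_obs = length(y), q_species = q_sp, q_pixel = q_px),
            class = "hb_posterior")
}

#' @export
print.hb_posterior <- function(x, ...) {
  cat(sprintf("<hb_posterior> variant=%s, %d chains x %d draws (n=%d)\n",
              x$variant, x$chains, x$iterations - x$burnin, x$n_obs))
  print(round(x$summary, 4))
  invisible(x)
}

#' Gelman-Rubin convergence diagnostic
#'
#' Potential-scale-reduction factor for one parameter traced by several
#' chains: with within-chain variance W and between-chain variance B (of
#' the chain means, times the chain length), `Rhat = sqrt((((n-1)/n) W +
#' B/n) / W)`. Values near 1 indicate the chains sample the same
#' distribution.
#'
#' @param draws Matrix with one column per chain (or list of equal-length
#'   numeric vectors).
#' @return Rhat (numeric scalar); NA with a warning when the within-chain
#'   variance is zero (degenerate chains).
#' @export
gelman_rubin <- function(draws) {
  if (is.list(draws)) draws <- do.call(cbind, draws)
  draws <- as.matrix(draws)
  if (ncol(draws) < 2) .stop_invalid("need at least 2 chains")
  n <- nrow(draws)
  W <- mean(apply(draws, 2, var))
  B <- n * var(colMeans(draws))
  if (!is.finite(W) || W == 0) {
    warning("degenerate chains: within-chain variance is zero")
    return(NA_real_)
  }
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Write an hb_posterior summary as CSV
#'
#' @param fit An `hb_posterior`.
#' @param path File path.
#' @export
write_hb_summary_csv <- function(fit, path) {
  out <- cbind(parameter = rownames(fit$summary), fit$summary)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
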