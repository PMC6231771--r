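test_that("two-SD standardization centers and halves the scale", {
  z <- standardize_2sd(c(1, 2, 3))
  expect_equal(as.numeric(z), c(-0.5, 0, 0.5))
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 0.5)
  z2 <- standardize_2sd(as.numeric(standardize_2sd(rnorm(50))))
  expect_equal(mean(z2), 0)
  expect_equal(sd(z2), 0.5)
  expect_error(standardize_2sd(rep(4, 10)), class = "phenosync_degenerate")
})

test_that("Gelman-Rubin statistic separates mixed from divergent chains", {
  expect_warning(r <- gelman_rubin(matrix(5, 100, 3)), "degenerate")
  expect_true(is.na(r))
  set.seed(14)
  mixed <- matrix(rnorm(4000 * 3), 4000, 3)
  expect_gt(gelman_rubin(mixed), 0.99)
  expect_lt(gelman_rubin(mixed), 1.05)
  apart <- cbind(rnorm(500), rnorm(500, 10))
  expect_gt(gelman_rubin(apart), 1.1)
  expect_error(gelman_rubin(matrix(1:10, ncol = 1)),
               class = "phenosync_invalid_parameter")
})

sim_hb_data <- function(seed, beta1 = 0.5, n_species = 10, n_pixels = 20,
                        sd_sp = 0.7, sd_px = 0.5, sd_res = 1) {
  set.seed(seed)
  d <- expand.grid(species = seq_len(n_species), pixel = seq_len(n_pixels))
  d$preseason_temp <- rnorm(nrow(d))
  d$dependent <- 1 + beta1 * d$preseason_temp +
    rnorm(n_species, 0, sd_sp)[d$species] +
    rnorm(n_pixels, 0, sd_px)[d$pixel] + rnorm(nrow(d), 0, sd_res)
  d
}

test_that("posterior concentrates on a planted slope and a null slope", {
  d <- sim_hb_data(81, beta1 = 0.5)
  fit <- fit_hb_model(d, "temperature", iterations = 4000, burnin = 1000,
                      seed = 5, standardize = FALSE)
  s <- fit$summary["beta_preseason_temp", ]
  expect_true(s$q2.5 <= 0.5 && 0.5 <= s$q97.5)
  expect_true(fit$converged)
  expect_true(all(fit$summary$rhat <= 1.1, na.rm = TRUE))

  d0 <- sim_hb_data(82, beta1 = 0)
  fit0 <- fit_hb_model(d0, "temperature", iterations = 4000, burnin = 1000,
                       seed = 6, standardize = FALSE)
  s0 <- fit0$summary["beta_preseason_temp", ]
  expect_true(s0$q2.5 <= 0 && 0 <= s0$q97.5)
})

test_that("a single species and pixel collapse to OLS within Monte Carlo error", {
  set.seed(4)
  d <- data.frame(preseason_temp = rnorm(40, 0, 1.5), species = "s", pixel = "p")
  d$dependent <- 2 + 0.8 * d$preseason_temp + rnorm(40, 0, 0.6)
  w <- capture_warnings(
    fit <- fit_hb_model(d, "temperature", iterations = 4000, burnin = 1000,
                        seed = 3, standardize = FALSE))
  expect_match(w, "random effect dropped", all = TRUE)
  expect_length(w, 2)
  ols <- coef(lm(dependent ~ preseason_temp, d))
  s <- fit$summary
  expect_equal(s["beta_preseason_temp", "mean"], unname(ols[2]),
               tolerance = 0.02)
  expect_equal(s["alpha", "mean"], unname(ols[1]), tolerance = 0.02)
  expect_equal(fit$q_species, 0L)
  expect_equal(fit$q_pixel, 0L)
})

test_that("posterior slope tracks the REML estimate on matched data", {
  d <- sim_hb_data(83)
  fit <- fit_hb_model(d, "temperature", iterations = 4000, burnin = 1000,
                      seed = 11, standardize = FALSE)
  m <- lme4::lmer(dependent ~ preseason_temp + (1 | species) + (1 | pixel),
                  data = d)
  expect_equal(fit$summary["beta_preseason_temp", "mean"],
               unname(lme4::fixef(m)[2]), tolerance = 0.05)
  expect_equal(fit$summary["sigma2", "mean"], stats::sigma(m)^2,
               tolerance = 0.15)
})

test_that("with no data the fixed effects sample their N(0, 1000) prior", {
  d <- data.frame(dependent = numeric(0), preseason_temp = numeric(0))
  fit <- fit_hb_model(d, "temperature", chains = 2, iterations = 3000,
                      burnin = 500, seed = 8, standardize = FALSE)
  draws <- unlist(lapply(fit$draws, function(m) m[, "alpha"]))
  expect_equal(sd(draws), sqrt(1000), tolerance = 0.1)
  expect_equal(mean(draws), 0, tolerance = 3)
})

test_that("relabelling species leaves the slope posterior invariant", {
  d <- sim_hb_data(84, n_species = 6, n_pixels = 8)
  fit1 <- fit_hb_model(d, "temperature", chains = 2, iterations = 3000,
                       burnin = 500, seed = 2, standardize = FALSE)
  d2 <- d
  d2$species <- c(4, 6, 1, 3, 2, 5)[d2$species]   # permute labels
  fit2 <- fit_hb_model(d2, "temperature", chains = 2, iterations = 3000,
                       burnin = 500, seed = 12, standardize = FALSE)
  mc_err <- 3 * fit1$summary["beta_preseason_temp", "sd"] / sqrt(500)
  expect_equal(fit1$summary["beta_preseason_temp", "mean"],
               fit2$summary["beta_preseason_temp", "mean"],
               tolerance = max(mc_err, 0.02))
})

test_that("the daylength-chilling variant fits both slopes", {
  set.seed(85)
  n <- 240
  d <- data.frame(daylength = rnorm(n), chilling = rnorm(n),
                  species = sample(1:6, n, TRUE),
                  pixel = sample(1:8, n, TRUE))
  d$dependent <- 1 - 0.6 * d$daylength + 0.3 * d$chilling + rnorm(n, 0, 0.7)
  fit <- fit_hb_model(d, "daylength_chilling", iterations = 3000,
                      burnin = 500, seed = 4, standardize = FALSE)
  s <- fit$summary
  expect_true(s["beta_daylength", "q2.5"] <= -0.6 &&
                -0.6 <= s["beta_daylength", "q97.5"])
  expect_true(s["beta_chilling", "q2.5"] <= 0.3 &&
                0.3 <= s["beta_chilling", "q97.5"])
})

test_that("standardized fits report effects on the 2-SD scale", {
  d <- sim_hb_data(86)
  fit <- fit_hb_model(d, "temperature", iterations = 3000, burnin = 500,
                      seed = 9)
  # cross-check against REML on identically standardized data
  ds <- d
  ds$dependent <- as.numeric(standardize_2sd(d$dependent))
  ds$preseason_temp <- as.numeric(standardize_2sd(d$preseason_temp))
  m <- lme4::lmer(dependent ~ preseason_temp + (1 | species) + (1 | pixel),
                  data = ds)
  expect_equal(fit$summary["beta_preseason_temp", "mean"],
               unname(lme4::fixef(m)[2]), tolerance = 0.05)
  # and the scale identity: beta_std = beta_raw * sd_x / sd_y
  expect_equal(fit$summary["beta_preseason_temp", "mean"],
               0.5 * sd(d$preseason_temp) / sd(d$dependent),
               tolerance = 0.25)
})
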