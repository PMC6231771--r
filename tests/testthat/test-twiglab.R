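test_that("first-k replicate means follow their definition", {
  x <- seq(3, 21, by = 2)
  expect_equal(as.numeric(mean_leafout_first_k(x, 8)), 10)
  expect_equal(as.numeric(mean_leafout_first_k(rep(12, 10), 8)), 12)
  expect_warning(m <- mean_leafout_first_k(c(4, 6, 8, 10, 12, 14, NA, NA, NA, NA), 8),
                 "6 of 8")
  expect_equal(as.numeric(m), 9)
  expect_true(attr(m, "incomplete"))
})

test_that("sensitivity slopes are OLS slopes and shift invariant", {
  expect_equal(daylength_sensitivity(c(300, 250, 200), c(8, 12, 16)), -12.5)
  expect_equal(daylength_sensitivity(c(200, 200, 200), c(8, 12, 16)), 0)
  expect_equal(chilling_sensitivity(c(400, 300, 200), c(500, 1000, 1500)), -0.2)
  expect_equal(chilling_sensitivity(c(250, 250), c(500, 1500)), 0)
  expect_equal(daylength_sensitivity(c(300, 250, 200) + 55, c(8, 12, 16)), -12.5)
  expect_error(daylength_sensitivity(200, 8),
               class = "phenosync_invalid_parameter")
  # an individual needing 2x the warming at 8 h vs 16 h is classified sensitive
  dd16 <- 180
  sl <- daylength_sensitivity(c(2 * dd16, 1.5 * dd16, dd16), c(8, 12, 16))
  expect_lt(sl, 0)
  expect_equal(abs(sl), dd16 / 8)
})

test_that("forcing requirement reads the long-chilling 16-h cell", {
  twigs <- data.frame(collection = rep(c("c1", "c3"), each = 4),
                      daylength_h = rep(c(8, 16), each = 2),
                      dd_at_leafout = c(400, 410, 300, 310, 250, 260, 180, 180),
                      leafout_date = c(40, 41, 30, 31, 25, 26, 18, 18))
  expect_equal(forcing_requirement(twigs, collection = "c3"), 180)
  expect_error(forcing_requirement(twigs[twigs$daylength_h == 8, ],
                                   collection = "c3"),
               class = "phenosync_missing_data")
})

test_that("planted traits are recovered from simulated twig observations", {
  set.seed(20)
  traits <- data.frame(individual_id = sprintf("t%02d", 1:11),
                       forcing_req = rnorm(11, 180, 30),
                       daylength_sens = seq(0, -27, length.out = 11),
                       chilling_sens = rnorm(11, -0.2, 0.03))
  chill <- c(dec = 500, feb = 1000, mar = 1500)
  twigs <- simulate_twig_observations(traits, chill, noise_sd = 5, seed = 77)
  est <- twig_traits(twigs, chill)
  est <- est[match(traits$individual_id, est$individual_id), ]
  expect_gt(cor(est$forcing_req, traits$forcing_req), 0.9)
  expect_gt(cor(est$daylength_sens, traits$daylength_sens), 0.9)
  expect_gt(cor(est$chilling_sens, traits$chilling_sens), 0.9)
  expect_equal(est$forcing_req, traits$forcing_req, tolerance = 0.1)
  # chilling slopes are homogeneous relative to day-length slopes
  expect_lt(sd(est$chilling_sens) * 1000, sd(est$daylength_sens) * 100)
})

test_that("sequential SS recovers exact orthogonal contributions", {
  po <- stats::poly(1:11, 3)
  traits <- data.frame(individual_id = sprintf("t%02d", 1:11),
                       forcing_req = po[, 1], daylength_sens = po[, 2],
                       chilling_sens = po[, 3])
  set.seed(6)
  leafout <- do.call(rbind, lapply(1:3, function(lev)
    data.frame(individual_id = traits$individual_id, chilling_level = lev,
               leafout = sqrt(50) * po[, 1] + sqrt(30) * po[, 2] +
                 sqrt(20) * po[, 3] + rnorm(11, 0, 1e-3))))
  shares <- partition_variance_anova(leafout, traits)
  expect_equal(nrow(shares), 3)
  for (i in 1:3) {
    expect_equal(shares$pct_forcing[i], 50, tolerance = 0.1)
    expect_equal(shares$pct_daylength[i], 30, tolerance = 0.1)
    expect_equal(shares$pct_chilling[i], 20, tolerance = 0.1)
    expect_lt(shares$pct_residual[i], 0.1)
  }
  expect_equal(shares$pct_forcing + shares$pct_daylength +
                 shares$pct_chilling + shares$pct_residual, rep(100, 3))
})

test_that("a single-cue response loads fully on that cue", {
  po <- stats::poly(1:11, 3)
  traits <- data.frame(individual_id = sprintf("t%02d", 1:11),
                       forcing_req = po[, 1], daylength_sens = po[, 2],
                       chilling_sens = po[, 3])
  leafout <- data.frame(individual_id = traits$individual_id,
                        chilling_level = 1, leafout = 5 * po[, 2])
  shares <- suppressWarnings(partition_variance_anova(leafout, traits))
  expect_equal(shares$pct_daylength, 100, tolerance = 1e-6)
  expect_lt(shares$pct_forcing + shares$pct_chilling + shares$pct_residual,
            1e-6)
})

test_that("pure-noise responses leave the residual share dominant", {
  set.seed(30)
  traits <- data.frame(individual_id = sprintf("t%02d", 1:11),
                       forcing_req = rnorm(11), daylength_sens = rnorm(11),
                       chilling_sens = rnorm(11))
  shares <- do.call(rbind, lapply(1:40, function(k)
    partition_variance_anova(
      data.frame(individual_id = traits$individual_id, chilling_level = 1,
                 leafout = rnorm(11)), traits)))
  # expected share of each 1-df predictor under the null is ~ 1/10 of SS
  expect_gt(mean(shares$pct_residual), 55)
  expect_lt(mean(shares$pct_forcing), 20)
  expect_lt(mean(shares$pct_daylength), 20)
  expect_lt(mean(shares$pct_chilling), 20)
})

test_that("variance components recover planted shares", {
  tw <- simulate_twig_experiment(var_individual = 52, var_treatment = 33,
                                 var_residual = 15, seed = 42)
  vc <- variance_components(tw)
  expect_equal(sum(vc$pct), 100)
  expect_equal(unname(vc$pct["residual"]), 15, tolerance = 0.35)
  # REML and moment estimates agree on balanced data
  vm <- variance_components(tw, method = "moments")
  expect_equal(vc$variances, vm$variances, tolerance = 1e-3)
})

test_that("degenerate variance structures land on the right component", {
  tw0 <- simulate_twig_experiment(var_individual = 0, var_treatment = 30,
                                  var_residual = 10, seed = 7)
  vc0 <- variance_components(tw0, method = "moments")
  expect_lt(vc0$pct["individual"], 10)
  twr <- simulate_twig_experiment(var_individual = 40, var_treatment = 30,
                                  var_residual = 1e-8, seed = 8)
  vcr <- suppressWarnings(variance_components(twr))
  expect_lt(vcr$pct["residual"], 1)
  expect_error(variance_components(
    data.frame(individual_id = "a", treatment = c("x", "y"),
               leafout = c(1, 2))),
    class = "phenosync_invalid_parameter")
})
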