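test_that("OLS reproduces the hand-solved 4-point interpolation exactly", {
  obs <- hand_observations()
  fit <- fit_male_tfr(obs, "age_gap")
  expect_equal(unname(coef(fit)), c(0, 1, -1), tolerance = 1e-10)
  expect_equal(unname(coef(fit)), unname(ols_by_hand(obs)), tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$resid_sd, 0, tolerance = 1e-10)
})

test_that("noiseless panels return the generating coefficients at machine precision", {
  coefs <- unname(age_gap_coefs)
  panel <- generate_regression_panel(200, coefs, noise_sd = 0, seed = 3)
  fit <- fit_male_tfr(panel)
  expect_equal(unname(coef(fit)), coefs, tolerance = 1e-10)
})

test_that("fit reports n-3 residual scale, R2 and a PSD covariance", {
  panel <- generate_regression_panel(500, unname(age_gap_coefs),
                                     noise_sd = 0.05, seed = 5)
  fit <- fit_male_tfr(panel)
  # independent residual-sd computation with denominator n - 3
  cf <- ols_by_hand(panel)
  res <- log(panel$tfr_male) -
    (cf[1] + cf[2] * log(panel$tfr_female) + cf[3] * log(panel$sex_ratio))
  expect_equal(fit$resid_sd, sqrt(sum(res^2) / (500 - 3)), tolerance = 1e-10)
  expect_true(fit$r_squared > 0 && fit$r_squared <= 1)
  expect_equal(fit$vcov, t(fit$vcov), tolerance = 1e-12)
  expect_true(all(eigen(fit$vcov, only.values = TRUE)$values > -1e-12))
  expect_equal(fit$n_obs, 500L)
})

test_that("degenerate inputs are rejected", {
  obs <- hand_observations()
  expect_error(fit_male_tfr(obs[1:2, ]), "at least 3")
  obs_bad <- obs; obs_bad$tfr_male[1] <- -1
  expect_error(fit_male_tfr(obs_bad), "strictly positive")
  collinear <- tibble::tibble(tfr_female = c(2, 3, 4, 5),
                              sex_ratio = c(2, 3, 4, 5),
                              tfr_male = c(2, 3, 4, 5))
  expect_error(fit_male_tfr(collinear), "collinear|singular")
})

test_that("predictions follow the log-linear form and its monotonicities", {
  fit <- male_tfr_fit_from_coefficients(age_gap_coefs)
  expect_equal(predict_male_tfr(fit, 1, 1)$point, exp(-0.078))
  # strictly increasing in tfr_female, strictly decreasing in sex_ratio
  tfrw <- seq(0.5, 6, by = 0.25)
  pts <- predict_male_tfr(fit, tfrw, 1)$point
  expect_true(all(diff(pts) > 0))
  srs <- seq(0.5, 2, by = 0.1)
  pts <- predict_male_tfr(fit, 2.1, srs)$point
  expect_true(all(diff(pts) < 0))
  # coefficients-only fits carry no interval
  expect_true(all(is.na(predict_male_tfr(fit, 2.1, 1)[c("pi_low", "pi_high")])))
  expect_error(predict_male_tfr(fit, -1, 1), "strictly positive")
})

test_that("the five replacement-level worked predictions hold at printed precision", {
  fit <- male_tfr_fit_from_coefficients(age_gap_coefs)
  expect_equal(round(predict_male_tfr(fit, 2.1, 1)$point, 2), 2.09)
  expect_equal(round(predict_male_tfr(fit, 2.1, 0.5)$point, 2), 3.31)
  expect_equal(round(predict_male_tfr(fit, 2.1, 2)$point, 2), 1.32)
  expect_equal(round(predict_male_tfr(fit, 1.0, 1)$point, 2), 0.92)
  expect_equal(round(predict_male_tfr(fit, 3.0, 1)$point, 1), 3.1)
})

test_that("prediction intervals contain the point, and width shrinks to the
           residual-only asymptote as n grows", {
  coefs <- unname(age_gap_coefs)
  widths <- sapply(c(50, 500, 5000), function(n) {
    fit <- fit_male_tfr(generate_regression_panel(n, coefs, 0.05, seed = 2))
    pr <- predict_male_tfr(fit, 2.1, 1)
    expect_true(pr$pi_low <= pr$point && pr$point <= pr$pi_high)
    log(pr$pi_high) - log(pr$pi_low)
  })
  # parameter variance (and the t quantile) shrink with n; the residual-sd
  # estimate fluctuates across panels, so only the large contrast is ordered
  expect_gt(widths[1], widths[3])
  # asymptotic width: 2 * z * resid_sd on the log scale
  fit <- fit_male_tfr(generate_regression_panel(5000, coefs, 0.05, seed = 2))
  asymptote <- 2 * qnorm(0.95) * fit$resid_sd
  expect_equal(widths[3], asymptote, tolerance = 0.01)
})

test_that("estimate_panel computes variant sex ratios and reports skips", {
  fit <- male_tfr_fit_from_coefficients(age_gap_coefs)
  # two regions differing only in sex ratio (1 vs 2): log tfr_male differs
  # by beta_sr * log 2 exactly
  pop <- dplyr::bind_rows(
    pop_frame(15:60, male = 100, female = 100, region_id = "A"),
    pop_frame(15:60, male = 200, female = 100, region_id = "B"))
  fert <- tibble::tibble(region_id = c("A", "B"), year = 2000,
                         tfr_female = 2.5, tfr_male = NA_real_)
  est <- estimate_panel(pop, fert, fit)
  expect_equal(est$sex_ratio, c(1, 2))
  expect_equal(log(est$tfr_male[2]) - log(est$tfr_male[1]),
               age_gap_coefs[["beta_sr"]] * log(2), tolerance = 1e-12)

  # missing population for one region-year is reported, not silent
  fert2 <- dplyr::bind_rows(fert, tibble::tibble(
    region_id = "C", year = 2000, tfr_female = 2, tfr_male = NA_real_))
  est2 <- estimate_panel(pop, fert2, fit)
  expect_length(attr(est2, "skipped"), 1)
  expect_match(attr(est2, "skipped"), "C/2000")
  expect_true(is.na(est2$tfr_male[3]))
})

test_that("estimated male/female TFR ratio is non-increasing as the SRB rises", {
  cfg <- constant_scenario(years = 1950:1989,
                           srb = seq(105, 125, length.out = 40))
  sc <- generate_scenario(cfg)
  fit <- male_tfr_fit_from_coefficients(age_gap_coefs)
  est <- estimate_panel(sc$population, sc$fertility, fit)
  ratio <- est$tfr_male / est$tfr_female
  # exact model identity at constant TFRw: log ratio is affine in log SR,
  # so it moves one-for-one with beta_sr * log(SR)
  expect_equal(log(ratio) - age_gap_coefs[["beta_sr"]] * log(est$sex_ratio),
               rep(log(ratio[1]) - age_gap_coefs[["beta_sr"]] *
                     log(est$sex_ratio[1]), 40), tolerance = 1e-12)
  # the adult sex ratio responds to the SRB ramp with an age-structure lag;
  # once both age windows contain ramped cohorts it rises and the ratio falls
  late <- 27:40
  expect_true(all(diff(est$sex_ratio[late]) > 0))
  expect_true(all(diff(ratio[late]) < 0))
  # ordering property across the whole series: higher SR, no higher ratio
  # (early years share one sex ratio, hence ties)
  expect_true(all(diff(ratio[order(est$sex_ratio)]) <= 0))
})

test_that("fitted 95% confidence intervals cover the generating elasticities
           at the nominal rate across replications", {
  coefs <- unname(age_gap_coefs)
  reps <- 400
  covered <- matrix(NA, reps, 2)
  for (r in seq_len(reps)) {
    fit <- fit_male_tfr(generate_regression_panel(4000, coefs, 0.05, seed = r))
    se <- sqrt(diag(fit$vcov))[2:3]
    est <- coef(fit)[c("beta_tfr", "beta_sr")]
    tq <- qt(0.975, 4000 - 3)
    covered[r, ] <- abs(est - coefs[2:3]) <= tq * se
  }
  # binomial 3-sigma band around the nominal 0.95 for 400 replications
  band <- 0.95 + c(-3, 3) * sqrt(0.95 * 0.05 / reps)
  for (j in 1:2) {
    expect_gte(mean(covered[, j]), band[1])
    expect_lte(mean(covered[, j]), band[2])
  }
})

test_that("out-of-sample validation recovers the known noise level and coverage", {
  coefs <- unname(age_gap_coefs)
  fit <- fit_male_tfr(generate_regression_panel(4000, coefs, 0.05, seed = 21))
  # noiseless holdout from the *fitted* coefficients: rmse exactly 0
  noiseless <- generate_regression_panel(100, unname(coef(fit)), 0, seed = 22)
  v0 <- validate_out_of_sample(fit, noiseless)
  expect_equal(v0$rmse, 0, tolerance = 1e-12)
  # holdout with known noise sd 0.05: rmse close to 0.05
  noisy <- generate_regression_panel(1000, unname(coef(fit)), 0.05, seed = 23)
  v1 <- validate_out_of_sample(fit, noisy)
  expect_lt(abs(v1$rmse - 0.05), 0.005)
  expect_error(validate_out_of_sample(fit, noiseless[0, ]), "empty")
})
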