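test_that("generated scenarios satisfy the population balancing equation exactly", {
  sc <- generate_scenario(constant_scenario(
    years = 1950:1964, srb = seq(104, 110, length.out = 15),
    tfr = seq(4, 2, length.out = 15)))
  pop <- sc$population
  lt <- sc$lifetable
  wide <- tidyr::pivot_wider(pop, names_from = "sex", values_from = "count")
  for (yr in 1950:1963) {
    now <- pop[pop$year == yr, ]
    nxt <- pop[pop$year == yr + 1, ]
    p <- lt[lt$year == yr, ]
    for (sx in c("male", "female")) {
      n0 <- now[now$sex == sx, ]; n0 <- n0[order(n0$age), ]
      n1 <- nxt[nxt$sex == sx, ]; n1 <- n1[order(n1$age), ]
      px <- p[p$sex == sx, ]; px <- px[order(px$age), ]
      survived <- n0$count[-nrow(n0)] * px$p[-nrow(px)]
      expect_identical(n1$count[-1], survived)
    }
  }
})

test_that("births are consistent with ASFR, female exposure and the SRB", {
  sc <- generate_scenario(constant_scenario(years = 1950:1959, srb = 108))
  b <- sc$births
  gt <- sc$ground_truth
  for (yr in c(1950, 1955, 1959)) {
    by_age <- b[b$year == yr & b$sex_of_child == "all", ]
    fpop <- sc$population[sc$population$year == yr &
                            sc$population$sex == "female", ]
    expected <- gt$asfr[, as.character(yr)] *
      fpop$count[match(15:55, fpop$age)]
    expect_equal(by_age$count[match(as.character(15:55), by_age$mother_age)],
                 unname(expected), tolerance = 1e-12)
    bm <- b$count[b$year == yr & b$sex_of_child == "male"]
    bw <- b$count[b$year == yr & b$sex_of_child == "female"]
    expect_equal(bm / bw, 1.08, tolerance = 1e-12)
    expect_equal(bm + bw, sum(by_age$count), tolerance = 1e-9)
  }
  # emitted female TFR equals the sum of generated ASFRs
  expect_equal(sc$fertility$tfr_female, unname(colSums(gt$asfr)),
               tolerance = 1e-9)
})

test_that("SRB 105 with any mortality gives age-0 population sex ratio 1.05;
           symmetric rates give ratio 1 everywhere", {
  sc <- generate_scenario(constant_scenario(years = 1950:1999, srb = 105))
  pop <- sc$population
  age0 <- tidyr::pivot_wider(pop[pop$age == 0, ], names_from = "sex",
                             values_from = "count")
  expect_equal(age0$male / age0$female, rep(1.05, 50), tolerance = 1e-12)

  sym <- generate_scenario(constant_scenario(years = 1950:1969, srb = 100,
                                             sex_gap = 1))
  wide <- tidyr::pivot_wider(sym$population, names_from = "sex",
                             values_from = "count")
  expect_equal(wide$male / wide$female, rep(1, nrow(wide)), tolerance = 1e-12)
})

test_that("a transient male hazard shock matches an independent cohort simulation", {
  shock <- list(years = c(1960, 1962), sex = "male", ages = c(18, 40),
                multiplier = 3)
  cfg <- constant_scenario(years = 1950:1975, shocks = list(shock))
  sc <- generate_scenario(cfg)
  gt <- sc$ground_truth
  pop <- sc$population

  # independent per-cohort oracle: follow each cohort born in-window through
  # the emitted survival matrices
  cohort_count <- function(birth_year, sex, target_year) {
    b <- sc$births
    n0 <- b$count[b$year == birth_year & b$sex_of_child == sex]
    surv <- gt$survival[[sex]]
    n <- n0
    for (y in birth_year:(target_year - 1)) {
      age <- y - birth_year
      n <- n * surv[age + 1, match(y, gt$years)]
    }
    n
  }
  for (by in c(1955, 1958)) {
    for (sx in c("male", "female")) {
      got <- pop$count[pop$year == 1970 & pop$sex == sx &
                         pop$age == 1970 - by]
      expect_equal(got, cohort_count(by, sx, 1970), tolerance = 1e-12)
    }
  }

  # the shock dips cohort sex ratios only where shocked cohorts pass through
  base <- generate_scenario(constant_scenario(years = 1950:1975))
  ratio_at <- function(s, year, age) {
    p <- s$population
    p$count[p$year == year & p$sex == "male" & p$age == age] /
      p$count[p$year == year & p$sex == "female" & p$age == age]
  }
  # a cohort aged 25 in 1961 was in the shocked window
  expect_lt(ratio_at(sc, 1970, 34), ratio_at(base, 1970, 34))
  # a cohort aged 10 during the shock was never exposed
  expect_equal(ratio_at(sc, 1965, 14), ratio_at(base, 1965, 14),
               tolerance = 1e-12)
})

test_that("regression panels follow the generating line and are reproducible", {
  coefs <- unname(age_gap_coefs)
  noiseless <- generate_regression_panel(50, coefs, noise_sd = 0, seed = 7)
  expect_equal(log(noiseless$tfr_male),
               coefs[1] + coefs[2] * log(noiseless$tfr_female) +
                 coefs[3] * log(noiseless$sex_ratio),
               tolerance = 1e-12)

  a <- generate_regression_panel(4000, coefs, noise_sd = 0.05, seed = 11)
  b <- generate_regression_panel(4000, coefs, noise_sd = 0.05, seed = 11)
  expect_identical(a, b)

  # CLT check: mean log-scale residual within 3 sd / sqrt(n) of zero
  resid <- log(a$tfr_male) - (coefs[1] + coefs[2] * log(a$tfr_female) +
                                coefs[3] * log(a$sex_ratio))
  expect_lt(abs(mean(resid)), 3 * 0.05 / sqrt(4000))
})

test_that("config validation rejects impossible scenarios", {
  expect_error(scenario_config(start_year = 2000, end_year = 1990),
               "end_year precedes")
  expect_error(scenario_config(srb = -1), "srb")
  expect_error(scenario_config(srb = c(105, 106)), "per year")
  expect_error(scenario_config(shocks = list(list(years = c(1, 2),
                                                  multiplier = 0))),
               "multiplier")
})
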