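# Shared fixtures, built in code at test time.

# Table-1 age-gap coefficient set used throughout the tests.
age_gap_coefs <- c(alpha = -0.078, beta_tfr = 1.101, beta_sr = -0.661)

# A small constant-rate scenario (no shocks) for cross-module oracles.
constant_scenario <- function(years = 1950:1965, srb = 105, sex_gap = 1.5,
                              tfr = 2.5, ...) {
  scenario_config(region_id = "SIM", start_year = min(years),
                  end_year = max(years), srb = srb, tfr = tfr,
                  mortality = list(level = 1e-4, slope = 0.09,
                                   sex_gap = sex_gap, infant = 0.01),
                  ...)
}

# Minimal population frame: one region-year, counts given per age for each sex.
pop_frame <- function(ages, male, female, region_id = "R1", year = 2000) {
  tibble::tibble(
    region_id = region_id, year = year,
    age = rep(ages, 2), sex = rep(c("male", "female"), each = length(ages)),
    count = c(rep_len(male, length(ages)), rep_len(female, length(ages))))
}

# Births-by-maternal-age frame (sex_of_child = "all").
births_frame <- function(ages, counts, region_id = "R1", year = 2000) {
  tibble::tibble(region_id = region_id, year = year, sex_of_child = "all",
                 mother_age = as.character(ages), count = counts)
}

# Flat life table at constant per-age survival for both sexes.
lifetable_frame <- function(p_male, p_female, max_age = 80,
                            region_id = "R1", year = 2000) {
  ages <- 0:max_age
  tibble::tibble(
    region_id = region_id, year = year,
    sex = rep(c("male", "female"), each = length(ages)),
    age = rep(ages, 2),
    p = c(rep_len(p_male, length(ages)), rep_len(p_female, length(ages))))
}

# Hand dataset with exact log2-proportional structure: OLS must interpolate
# with alpha = 0, beta_tfr = 1, beta_sr = -1.
hand_observations <- function() {
  tibble::tibble(tfr_female = c(2, 4, 2, 4), sex_ratio = c(1, 1, 2, 2),
                 tfr_male = c(2, 4, 1, 2))
}

# Independent OLS by explicit normal equations (the oracle for fit_male_tfr).
ols_by_hand <- function(obs) {
  X <- cbind(1, log(obs$tfr_female), log(obs$sex_ratio))
  y <- log(obs$tfr_male)
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}
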