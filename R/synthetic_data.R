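#' Scenario configuration for the cohort-component generator
#'
#' Bundles everything the migration-free generator needs: a per-year sex
#' ratio at birth path (male births per 100 female births; naturally about
#' 103--107, higher under sex-selective abortion), a per-year female TFR path,
#' a two-parameter fertility age schedule over ages 15--55, parametric
#' sex-specific mortality, and optional transient hazard shocks (conflict or
#' maternal-mortality episodes).
#'
#' Mortality is a Gompertz hazard `level * exp(slope * age)` with a
#' multiplicative male gap factor and an additive infant component
#' `infant * exp(-age)`; survival is `p(x) = exp(-hazard(x))`. Scalar
#' `srb` / `tfr` are recycled across years.
#'
#' @param region_id Region label for the emitted frames.
#' @param start_year,end_year Inclusive calendar-year range.
#' @param srb Sex ratio at birth path: scalar or one value per year.
#' @param tfr Female TFR path: scalar or one value per year.
#' @param fertility_mean_age,fertility_sd_age Location and spread (years) of
#'   the symmetric-beta fertility schedule on ages 15--55.
#' @param mortality List with `level`, `slope`, `sex_gap` (male hazard
#'   multiplier), `infant` (additive infant/young-child hazard at age 0).
#' @param shocks Optional list of shocks, each a list with `years` (length-2
#'   inclusive range), `sex` (`"male"`, `"female"` or `"both"`), `ages`
#'   (length-2 inclusive range) and `multiplier` (> 0) applied to the hazard.
#' @param base_female_births Annual female births anchoring the initial
#'   stationary population.
#' @param max_age Highest tracked single age (open interval stored here).
#' @param seed Integer seed recorded with the scenario (the projection itself
#'   is deterministic; counts are expected values).
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(region_id = "SIM", start_year = 1950,
                            end_year = 2000, srb = 105, tfr = 2.5,
                            fertility_mean_age = 28, fertility_sd_age = 6,
                            mortality = list(level = 1e-4, slope = 0.09,
                                             sex_gap = 1.5, infant = 0.01),
                            shocks = list(), base_female_births = 1e4,
                            max_age = 100L, seed = 1L) {
  if (end_year < start_year) {
    stop("config error: end_year precedes start_year", call. = FALSE)
  }
  years <- seq(start_year, end_year)
  expand <- function(x, what) {
    if (length(x) == 1) x <- rep(x, length(years))
    if (length(x) != length(years)) {
      stop("config error: ", what, " must have length 1 or one value per year",
           call. = FALSE)
    }
    x
  }
  srb <- expand(srb, "srb")
  tfr <- expand(tfr, "tfr")
  if (any(srb <= 0)) stop("config error: srb values must be > 0", call. = FALSE)
  if (any(tfr < 0)) stop("config error: tfr values must be >= 0", call. = FALSE)
  for (s in shocks) {
    if (!is.list(s) || is.null(s$years) || is.null(s$multiplier)) {
      stop("config error: each shock needs 'years' and 'multiplier'", call. = FALSE)
    }
    if (s$multiplier <= 0) {
      stop("config error: shock multiplier must be > 0", call. = FALSE)
    }
  }
  structure(list(region_id = region_id, years = years, srb = srb, tfr = tfr,
                 fertility_mean_age = fertility_mean_age,
                 fertility_sd_age = fertility_sd_age,
                 mortality = mortality, shocks = shocks,
                 base_female_births = base_female_births,
                 max_age = as.integer(max_age), seed = as.integer(seed)),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config> region", x$region_id, "years",
      min(x$years), "-", max(x$years), "\n")
  cat("  SRB", min(x$srb), "-", max(x$srb), "| TFR", min(x$tfr), "-",
      max(x$tfr), "| shocks:", length(x$shocks), "\n")
  invisible(x)
}

# Symmetric-beta fertility weights over single ages 15..55, normalized to
# sum to 1; mean/sd are mapped to beta shapes by method of moments.
.fertility_weights <- function(mean_age, sd_age, ages = 15:55) {
  lo <- 15; hi <- 56  # density support [15, 56): completed ages 15..55
  m <- (mean_age - lo) / (hi - lo)
  v <- (sd_age / (hi - lo))^2
  v <- min(v, m * (1 - m) * 0.999)
  common <- m * (1 - m) / v - 1
  a <- m * common
  b <- (1 - m) * common
  w <- stats::dbeta((ages + 0.5 - lo) / (hi - lo), a, b)
  w / sum(w)
}

# Hazard for one sex at single ages 0..max_age in one calendar year,
# including any shock multipliers active that year.
.hazard <- function(config, sex, year) {
  ages <- 0:config$max_age
  m <- config$mortality
  h <- m$level * exp(m$slope * ages) + m$infant * exp(-ages)
  if (sex == "male") h <- h * m$sex_gap
  for (s in config$shocks) {
    s_sex <- if (is.null(s$sex)) "both" else s$sex
    if (year >= s$years[1] && year <= s$years[2] &&
        (s_sex == "both" || s_sex == sex)) {
      in_ages <- ages >= s$ages[1] & ages <= s$ages[2]
      h[in_ages] <- h[in_ages] * s$multiplier
    }
  }
  h
}

.survival <- function(config, sex, year) exp(-.hazard(config, sex, year))

#' Generate an internally consistent demographic scenario
#'
#' Runs a migration-free cohort-component projection and emits the four
#' interchange frames plus ground truth. The projection satisfies the
#' population balancing equation exactly: for every year and sex,
#' `P(age + 1, year + 1) = P(age, year) * p(age, year)`, newborns enter at
#' age 0 in their birth year, births by maternal age equal
#' `ASFR(age, year) * P_female(age, year)`, and male over female births equal
#' `SRB(year) / 100`. The initial population is the stationary population
#' implied by the first year's survival schedule, which makes period
#' population sex ratios equal the synthetic-cohort sex ratio at every age
#' whenever rates are constant in time.
#'
#' @param config A [scenario_config()].
#' @return A list with `population`, `births`, `lifetable`, `fertility`
#'   tibbles (interchange schemas) and `ground_truth` (realized per-year SRB,
#'   survival probabilities, ASFRs and female TFR).
#' @export
generate_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  years <- config$years
  ages <- 0:config$max_age
  fert_ages <- 15:55
  w <- .fertility_weights(config$fertility_mean_age, config$fertility_sd_age,
                          fert_ages)

  n_age <- length(ages)
  # survival probabilities p[age+1, year, sex]
  p_m <- vapply(years, function(y) .survival(config, "male", y),
                numeric(n_age))
  p_f <- vapply(years, function(y) .survival(config, "female", y),
                numeric(n_age))

  # initial stationary population: cohort size base * cumulative survivorship
  lx <- function(p) cumprod(c(1, p[-n_age]))
  srb0 <- config$srb[1]
  pop_f <- config$base_female_births * lx(p_f[, 1])
  pop_m <- config$base_female_births * (srb0 / 100) * lx(p_m[, 1])

  pop_rows <- vector("list", length(years))
  birth_rows <- vector("list", length(years))
  asfr_mat <- matrix(0, nrow = length(fert_ages), ncol = length(years),
                     dimnames = list(fert_ages, years))
  for (t in seq_along(years)) {
    year <- years[t]
    if (t > 1) {
      pop_f <- c(0, (pop_f * p_f[, t - 1])[-n_age])
      pop_m <- c(0, (pop_m * p_m[, t - 1])[-n_age])
    }
    asfr <- config$tfr[t] * w
    asfr_mat[, t] <- asfr
    births_by_age <- asfr * pop_f[fert_ages + 1]
    total_births <- sum(births_by_age)
    srb <- config$srb[t]
    births_m <- total_births * srb / (100 + srb)
    births_f <- total_births * 100 / (100 + srb)
    pop_m[1] <- births_m
    pop_f[1] <- births_f

    pop_rows[[t]] <- tibble::tibble(
      region_id = config$region_id, year = year,
      age = rep(ages, 2), sex = rep(c("male", "female"), each = n_age),
      count = c(pop_m, pop_f))
    birth_rows[[t]] <- tibble::tibble(
      region_id = config$region_id, year = year,
      sex_of_child = c(rep("all", length(fert_ages)), "male", "female"),
      mother_age = c(as.character(fert_ages), "all", "all"),
      count = c(births_by_age, births_m, births_f))
  }

  lifetable <- tibble::tibble(
    region_id = config$region_id,
    year = rep(rep(years, each = n_age), 2),
    sex = rep(c("male", "female"), each = n_age * length(years)),
    age = rep(ages, 2 * length(years)),
    p = c(as.vector(p_m), as.vector(p_f)))

  fertility <- tibble::tibble(
    region_id = config$region_id, year = years,
    tfr_female = vapply(seq_along(years), function(t) sum(asfr_mat[, t]),
                        numeric(1)),
    tfr_male = NA_real_)

  ground_truth <- list(
    srb = stats::setNames(config$srb, years),
    survival = list(male = p_m, female = p_f),
    ages = ages, years = years,
    asfr = asfr_mat,
    tfr_female = stats::setNames(colSums(asfr_mat), years),
    seed = config$seed)

  list(population = validate_frame(dplyr::bind_rows(pop_rows), "population"),
       births = validate_frame(dplyr::bind_rows(birth_rows), "births"),
       lifetable = validate_frame(lifetable, "lifetable"),
       fertility = validate_frame(fertility, "fertility"),
       ground_truth = ground_truth)
}

#' Generate a synthetic regression panel from the male-TFR model
#'
#' Draws covariates and generates male TFRs from the log-log model
#' `log(TFRm) = alpha + beta_tfr * log(TFRw) + beta_sr * log(SR) + eps`,
#' `eps ~ Normal(0, noise_sd^2)`. Default covariate design: `log(TFRw)`
#' uniform on `[log 0.8, log 8]` and `log(SR)` normal with sd 0.15 around a
#' balanced population.
#'
#' @param n Number of observations (>= 3).
#' @param coefficients Numeric vector `c(alpha, beta_tfr, beta_sr)`.
#' @param noise_sd Log-scale residual standard deviation (>= 0).
#' @param tfr_range Range of female TFR (natural scale) for the uniform draw.
#' @param log_sr_sd Standard deviation of the normal log sex-ratio draw.
#' @param seed Integer seed; panels are reproducible given the seed.
#' @return A tibble with `tfr_female`, `sex_ratio`, `tfr_male`.
#' @export
#' @examples
#' panel <- generate_regression_panel(10, c(-0.078, 1.101, -0.661),
#'                                    noise_sd = 0, seed = 1)
#' all.equal(log(panel$tfr_male),
#'           -0.078 + 1.101 * log(panel$tfr_female) -
#'             0.661 * log(panel$sex_ratio))
generate_regression_panel <- function(n, coefficients, noise_sd = 0.05,
                                      tfr_range = c(0.8, 8),
                                      log_sr_sd = 0.15, seed = 1L) {
  stopifnot(n >= 3, noise_sd >= 0, length(coefficients) == 3)
  set.seed(seed)
  log_tfrw <- stats::runif(n, log(tfr_range[1]), log(tfr_range[2]))
  log_sr <- stats::rnorm(n, 0, log_sr_sd)
  eps <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else rep(0, n)
  log_tfrm <- coefficients[1] + coefficients[2] * log_tfrw +
    coefficients[3] * log_sr + eps
  tibble::tibble(tfr_female = exp(log_tfrw), sex_ratio = exp(log_sr),
                 tfr_male = exp(log_tfrm))
}

#' Write a generated scenario to disk
#'
#' Emits the four interchange CSVs plus a `ground_truth.json` into `dir`.
#'
#' @param scenario Output of [generate_scenario()].
#' @param dir Output directory (created if missing).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(population = file.path(dir, "population.csv"),
             births = file.path(dir, "births.csv"),
             lifetable = file.path(dir, "lifetable.csv"),
             fertility = file.path(dir, "fertility.csv"))
  for (kind in names(paths)) {
    write_frame(scenario[[kind]], paths[[kind]], kind)
  }
  gt <- scenario$ground_truth
  gt_json <- list(srb = as.list(gt$srb), tfr_female = as.list(gt$tfr_female),
                  years = gt$years, seed = gt$seed)
  gt_path <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(gt_json, gt_path, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, ground_truth = gt_path))
}
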