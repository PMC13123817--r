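#' Model variants for the male-TFR regression
#'
#' The three variants differ only in the age ranges entering the adult sex
#' ratio: `baseline` compares men and women 20--39, `postponement` 25--44,
#' and `age_gap` compares men 25--44 with women 20--39 to reflect the typical
#' age gap between partners at childbirth.
#'
#' @param name One of `"baseline"`, `"postponement"`, `"age_gap"`.
#' @return A list with `name`, `male_ages`, `female_ages` (inclusive ranges).
#' @export
#' @examples
#' model_variant("age_gap")
model_variant <- function(name = c("baseline", "postponement", "age_gap")) {
  name <- match.arg(name)
  ranges <- switch(name,
    baseline     = list(male_ages = c(20L, 39L), female_ages = c(20L, 39L)),
    postponement = list(male_ages = c(25L, 44L), female_ages = c(25L, 44L)),
    age_gap      = list(male_ages = c(25L, 44L), female_ages = c(20L, 39L)))
  c(list(name = name), ranges)
}

#' Published coefficient sets for the male-TFR regression
#'
#' Point estimates of `(alpha, beta_tfr, beta_sr)` for the three model
#' variants as fitted on the harmonized male-TFR compilation (n = 4,024
#' country-years). They ship as a usable default so male TFRs can be
#' estimated without refitting; with coefficients only (no covariance or
#' residual scale) predictions carry no intervals.
#'
#' @param variant Variant name, as in [model_variant()].
#' @return Named numeric vector `c(alpha, beta_tfr, beta_sr)`.
#' @export
#' @examples
#' default_coefficients("age_gap")
default_coefficients <- function(variant = c("age_gap", "baseline",
                                             "postponement")) {
  variant <- match.arg(variant)
  switch(variant,
    baseline     = c(alpha = -0.092, beta_tfr = 1.182, beta_sr = -0.887),
    postponement = c(alpha = -0.114, beta_tfr = 1.197, beta_sr = -0.849),
    age_gap      = c(alpha = -0.078, beta_tfr = 1.101, beta_sr = -0.661))
}

.new_male_tfr_fit <- function(variant, coefficients, vcov = NULL,
                              resid_sd = NULL, n_obs = NA_integer_,
                              r_squared = NA_real_, adj_r_squared = NA_real_) {
  structure(list(variant = variant,
                 coefficients = coefficients,
                 vcov = vcov, resid_sd = resid_sd, n_obs = n_obs,
                 r_squared = r_squared, adj_r_squared = adj_r_squared),
            class = "male_tfr_fit")
}

#' Fit the male-TFR regression
#'
#' Ordinary least squares for `log(TFRm) = alpha + beta_tfr * log(TFRw) +
#' beta_sr * log(SR) + eps` on country-year observations, pooled and
#' unweighted, with classical standard errors. The residual scale uses the
#' usual denominator `n - 3`.
#'
#' @param observations Data frame with positive columns `tfr_male`,
#'   `tfr_female`, `sex_ratio`.
#' @param variant A [model_variant()] or variant name; recorded on the fit
#'   and used later by [estimate_panel()] to pick the sex-ratio age ranges.
#' @return A `male_tfr_fit` with coefficients, coefficient covariance,
#'   residual sd, `n_obs`, R-squared and adjusted R-squared.
#' @export
fit_male_tfr <- function(observations, variant = "age_gap") {
  if (is.character(variant)) variant <- model_variant(variant)
  need <- c("tfr_male", "tfr_female", "sex_ratio")
  missing_cols <- setdiff(need, names(observations))
  if (length(missing_cols) > 0) {
    stop("schema error: missing column(s) ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  obs <- observations[need]
  if (nrow(obs) < 3) stop("domain error: need at least 3 observations", call. = FALSE)
  if (any(!is.finite(as.matrix(obs))) || any(as.matrix(obs) <= 0)) {
    stop("domain error: tfr_male, tfr_female and sex_ratio must be strictly positive",
         call. = FALSE)
  }
  dat <- data.frame(y = log(obs$tfr_male), x1 = log(obs$tfr_female),
                    x2 = log(obs$sex_ratio))
  fit <- stats::lm(y ~ x1 + x2, data = dat)
  if (fit$rank < 3) {
    stop("singularity error: regressors are collinear (rank-deficient design)",
         call. = FALSE)
  }
  # summary.lm warns on exact interpolation ("essentially perfect fit");
  # noiseless panels are a supported input here, so muffle that warning only
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  cf <- stats::coef(fit)
  .new_male_tfr_fit(
    variant = variant,
    coefficients = c(alpha = unname(cf[1]), beta_tfr = unname(cf[2]),
                     beta_sr = unname(cf[3])),
    vcov = sm$cov.unscaled * sm$sigma^2,
    resid_sd = sm$sigma,
    n_obs = nrow(obs),
    r_squared = sm$r.squared,
    adj_r_squared = sm$adj.r.squared)
}

#' Build a fit object from published coefficients
#'
#' Wraps a bare `(alpha, beta_tfr, beta_sr)` coefficient set (for instance
#' [default_coefficients()]) as a `male_tfr_fit` without covariance or
#' residual scale. Predictions from such a fit are point estimates only;
#' interval bounds are `NA`.
#'
#' @param coefficients Numeric vector `c(alpha, beta_tfr, beta_sr)`.
#' @inheritParams fit_male_tfr
#' @return A `male_tfr_fit`.
#' @export
male_tfr_fit_from_coefficients <- function(coefficients, variant = "age_gap") {
  if (is.character(variant)) variant <- model_variant(variant)
  stopifnot(length(coefficients) == 3)
  coefficients <- stats::setNames(as.numeric(coefficients),
                                  c("alpha", "beta_tfr", "beta_sr"))
  .new_male_tfr_fit(variant = variant, coefficients = coefficients)
}

#' @export
print.male_tfr_fit <- function(x, ...) {
  cat("<male_tfr_fit> variant:", x$variant$name, "\n")
  cat(sprintf("  log(TFRm) = %.4f %+.4f log(TFRw) %+.4f log(SR)\n",
              x$coefficients["alpha"], x$coefficients["beta_tfr"],
              x$coefficients["beta_sr"]))
  if (!is.null(x$resid_sd)) {
    cat(sprintf("  n = %d, resid sd = %.4f, R2 = %.4f (adj %.4f)\n",
                x$n_obs, x$resid_sd, x$r_squared, x$adj_r_squared))
  } else {
    cat("  coefficients only (no covariance): predictions carry no intervals\n")
  }
  invisible(x)
}

#' @export
coef.male_tfr_fit <- function(object, ...) object$coefficients

#' Predict male TFR from female TFR and the adult sex ratio
#'
#' Point prediction `exp(alpha + beta_tfr * log(tfr_female) + beta_sr *
#' log(sex_ratio))` with a log-scale normal-theory prediction interval:
#' t quantile on `n - 3` degrees of freedom times the full prediction
#' standard error (parameter variance `x'Vx` plus residual variance),
#' exponentiated. Fits built from coefficients alone return the point with
#' `NA` interval bounds.
#'
#' @param fit A `male_tfr_fit`.
#' @param tfr_female Positive female TFR (vectorized).
#' @param sex_ratio Positive adult sex ratio (vectorized).
#' @param pi_level Prediction-interval level in (0, 1); default 0.90.
#' @return A tibble with `point`, `pi_low`, `pi_high`, `log_point`, `log_se`.
#' @export
#' @examples
#' fit <- male_tfr_fit_from_coefficients(default_coefficients("age_gap"))
#' predict_male_tfr(fit, tfr_female = 2.1, sex_ratio = 1)$point # ~2.09
predict_male_tfr <- function(fit, tfr_female, sex_ratio, pi_level = 0.90) {
  stopifnot(inherits(fit, "male_tfr_fit"), pi_level > 0, pi_level < 1)
  if (any(tfr_female <= 0) || any(sex_ratio <= 0)) {
    stop("domain error: tfr_female and sex_ratio must be strictly positive",
         call. = FALSE)
  }
  k <- max(length(tfr_female), length(sex_ratio))
  tfr_female <- rep_len(tfr_female, k)
  sex_ratio <- rep_len(sex_ratio, k)
  X <- cbind(1, log(tfr_female), log(sex_ratio))
  log_point <- as.vector(X %*% fit$coefficients)
  if (is.null(fit$vcov) || is.null(fit$resid_sd)) {
    log_se <- rep(NA_real_, k)
    lo <- hi <- rep(NA_real_, k)
  } else {
    param_var <- rowSums((X %*% fit$vcov) * X)
    log_se <- sqrt(param_var + fit$resid_sd^2)
    tq <- stats::qt(1 - (1 - pi_level) / 2, df = fit$n_obs - 3)
    lo <- exp(log_point - tq * log_se)
    hi <- exp(log_point + tq * log_se)
  }
  tibble::tibble(point = exp(log_point), pi_low = lo, pi_high = hi,
                 log_point = log_point, log_se = log_se)
}

#' Estimate male TFRs across a fertility panel
#'
#' For every region-year of the fertility table, computes the fit variant's
#' adult sex ratio from the population table and predicts the male TFR.
#' Region-years whose population does not cover the variant's age ranges are
#' skipped and reported in the `skipped` attribute rather than dropped
#' silently.
#'
#' @param pop Population frame covering the variant's age ranges.
#' @param fert Fertility frame (`tfr_female` used; `tfr_male` overwritten).
#' @param fit A `male_tfr_fit`.
#' @param pi_level Prediction-interval level passed to [predict_male_tfr()].
#' @return The fertility tibble with `tfr_male`, `tfr_male_pi_low`,
#'   `tfr_male_pi_high` and `sex_ratio` columns; skipped rows (with reasons)
#'   in `attr(, "skipped")`.
#' @export
estimate_panel <- function(pop, fert, fit, pi_level = 0.90) {
  stopifnot(inherits(fit, "male_tfr_fit"))
  v <- fit$variant
  out <- tibble::as_tibble(fert)
  out$sex_ratio <- NA_real_
  out$tfr_male <- NA_real_
  out$tfr_male_pi_low <- NA_real_
  out$tfr_male_pi_high <- NA_real_
  skipped <- character(0)
  for (i in seq_len(nrow(out))) {
    sr <- tryCatch(
      adult_sex_ratio(pop, out$region_id[i], out$year[i],
                      v$male_ages, v$female_ages),
      error = function(e) conditionMessage(e))
    if (is.character(sr)) {
      skipped <- c(skipped, paste0(out$region_id[i], "/", out$year[i], ": ", sr))
      next
    }
    if (out$tfr_female[i] <= 0) {
      skipped <- c(skipped, paste0(out$region_id[i], "/", out$year[i],
                                   ": nonpositive tfr_female"))
      next
    }
    pr <- predict_male_tfr(fit, out$tfr_female[i], sr, pi_level)
    out$sex_ratio[i] <- sr
    out$tfr_male[i] <- pr$point
    out$tfr_male_pi_low[i] <- pr$pi_low
    out$tfr_male_pi_high[i] <- pr$pi_high
  }
  attr(out, "skipped") <- skipped
  out
}

#' Out-of-sample validation of a male-TFR fit
#'
#' Log-scale root mean squared error and prediction-interval coverage on a
#' holdout set with observed male TFRs.
#'
#' @param fit A `male_tfr_fit` with covariance and residual scale.
#' @param holdout Data frame with positive `tfr_male`, `tfr_female`,
#'   `sex_ratio`.
#' @param pi_level Interval level for the coverage check; default 0.90.
#' @return A list with `rmse` (log scale) and `pi_coverage` (fraction of
#'   observed male TFRs inside the interval; `NA` when the fit carries no
#'   interval machinery).
#' @export
validate_out_of_sample <- function(fit, holdout, pi_level = 0.90) {
  if (is.null(holdout) || nrow(holdout) == 0) {
    stop("domain error: holdout is empty", call. = FALSE)
  }
  pr <- predict_male_tfr(fit, holdout$tfr_female, holdout$sex_ratio, pi_level)
  rmse <- sqrt(mean((log(holdout$tfr_male) - pr$log_point)^2))
  pi_coverage <- if (all(is.na(pr$pi_low))) NA_real_ else {
    mean(holdout$tfr_male >= pr$pi_low & holdout$tfr_male <= pr$pi_high)
  }
  list(rmse = rmse, pi_coverage = pi_coverage)
}
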