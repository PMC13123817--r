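#' Percent difference between male and female TFR
#'
#' `100 * (tfr_male - tfr_female) / tfr_female`: positive values mean higher
#' male fertility, negative values higher female fertility.
#'
#' @param tfr_male Male TFR (vectorized).
#' @param tfr_female Positive female TFR (vectorized).
#' @return Percent difference.
#' @export
#' @examples
#' percent_difference(3, 2)   # +50
#' percent_difference(1, 2.6) # about -61.5
percent_difference <- function(tfr_male, tfr_female) {
  if (any(tfr_female <= 0)) {
    stop("domain error: tfr_female must be strictly positive", call. = FALSE)
  }
  100 * (tfr_male - tfr_female) / tfr_female
}

#' Detect the male-to-female fertility crossover
#'
#' First year in which the male TFR falls strictly below the female TFR;
#' exact ties are not a crossover. Years must be strictly increasing with no
#' gaps.
#'
#' @param series Data frame with `year`, `tfr_male`, `tfr_female` columns,
#'   year-ordered.
#' @return Integer year, or `NA_integer_` if the male TFR never falls below.
#' @export
detect_crossover <- function(series) {
  yr <- series$year
  if (is.unsorted(yr, strictly = TRUE) || (length(yr) > 1 && any(diff(yr) != 1))) {
    stop("input error: years must be strictly increasing without gaps",
         call. = FALSE)
  }
  below <- which(series$tfr_male < series$tfr_female)
  if (length(below) == 0) NA_integer_ else as.integer(yr[below[1]])
}

#' Crossover analytics for one region's TFR series
#'
#' Per-year percent differences, the crossover year (if any), and the year of
#' the minimum percent difference.
#'
#' @inheritParams detect_crossover
#' @param region_id Region label carried into the result.
#' @return A list of class `crossover_result` with `region_id`,
#'   `pct_diff_series` (tibble of `year`, `pct_diff`), `crossover_year` and
#'   `min_pct_diff_year`.
#' @export
crossover_result <- function(series, region_id = "region") {
  pct <- percent_difference(series$tfr_male, series$tfr_female)
  structure(list(
    region_id = region_id,
    pct_diff_series = tibble::tibble(year = as.integer(series$year),
                                     pct_diff = pct),
    crossover_year = detect_crossover(series),
    min_pct_diff_year = as.integer(series$year[which.min(pct)])),
    class = "crossover_result")
}

#' @export
print.crossover_result <- function(x, ...) {
  cat("<crossover_result>", x$region_id, "\n")
  cat("  crossover year:",
      if (is.na(x$crossover_year)) "none" else x$crossover_year,
      "| min pct diff:",
      sprintf("%.2f%% in %d",
              min(x$pct_diff_series$pct_diff), x$min_pct_diff_year), "\n")
  invisible(x)
}

#' Per-year shares of regions and population by fertility sign
#'
#' For each year: the fraction of regions with strictly higher male than
#' female TFR, and the population-weighted share living in regions whose
#' male TFR is more than 5% below the female TFR (strictly
#' `pct_diff < -threshold`; a region at exactly -5% is not counted).
#'
#' @param panel Fertility frame with `tfr_male` filled.
#' @param pop_totals Data frame with `region_id`, `year`, `population` (total
#'   persons, all ages and sexes) used as weights.
#' @param threshold Percent threshold for the weighted share; default 5.
#' @return A tibble per year with `share_higher_male` and
#'   `popshare_below_minus5`; region-years lacking weights are listed in the
#'   `skipped` attribute.
#' @export
share_summary <- function(panel, pop_totals, threshold = 5) {
  merged <- dplyr::left_join(tibble::as_tibble(panel), pop_totals,
                             by = c("region_id", "year"))
  skipped <- merged[is.na(merged$population) | is.na(merged$tfr_male), ]
  kept <- merged[!(is.na(merged$population) | is.na(merged$tfr_male)), ]
  out <- dplyr::summarise(
    dplyr::group_by(kept, .data$year),
    share_higher_male = mean(.data$tfr_male > .data$tfr_female),
    popshare_below_minus5 = sum(.data$population *
      (percent_difference(.data$tfr_male, .data$tfr_female) < -threshold)) /
      sum(.data$population),
    .groups = "drop")
  attr(out, "skipped") <- paste0(skipped$region_id, "/", skipped$year)
  out
}

#' Counterfactual decomposition of a TFR-ratio change
#'
#' Under the log-log model, `log(TFRm / TFRw) = alpha + (beta_tfr - 1) *
#' log(TFRw) + beta_sr * log(SR)`, so a change in the log TFR ratio between
#' two states splits exactly into a fertility-level component
#' `(beta_tfr - 1) * (log tfrw_1 - log tfrw_0)` and a sex-ratio component
#' `beta_sr * (log sr_1 - log sr_0)`. The components are additive and
#' order-independent.
#'
#' @param fit A `male_tfr_fit` (or bare coefficient vector).
#' @param tfrw_0,sr_0 Baseline female TFR and sex ratio (> 0).
#' @param tfrw_1,sr_1 Comparison female TFR and sex ratio (> 0).
#' @return A list with `total` (change in log TFR ratio), `tfrw_component`,
#'   `sr_component`; the components sum to the total exactly.
#' @export
counterfactual_ratio_decomposition <- function(fit, tfrw_0, sr_0, tfrw_1, sr_1) {
  cf <- if (inherits(fit, "male_tfr_fit")) fit$coefficients else fit
  stopifnot(length(cf) == 3)
  if (any(c(tfrw_0, sr_0, tfrw_1, sr_1) <= 0)) {
    stop("domain error: all inputs must be strictly positive", call. = FALSE)
  }
  tfrw_component <- (cf[[2]] - 1) * (log(tfrw_1) - log(tfrw_0))
  sr_component <- cf[[3]] * (log(sr_1) - log(sr_0))
  list(total = tfrw_component + sr_component,
       tfrw_component = tfrw_component, sr_component = sr_component)
}
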