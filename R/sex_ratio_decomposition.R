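#' Decompose the period age-specific population sex ratio
#'
#' Synthetic-cohort decomposition of the sex ratio at each age into a birth
#' contribution and a mortality contribution. The male radix is set to the
#' observed sex ratio at birth (male births per 100 female births) and the
#' female radix to 100; both are carried forward with the year's sex-specific
#' survival probabilities:
#'
#' \deqn{SR_t(x) = 100 \times \frac{B_m}{B_w} \times
#'   \frac{\prod_{i=0}^{x-1} p_m(i)}{\prod_{i=0}^{x-1} p_w(i)}}
#'
#' The survivorship product runs from birth to exact age `x` (empty at
#' `x = 0`), so `sr_total(0)` equals the sex ratio at birth, and
#' `sr_total = birth_contribution * mortality_contribution` holds exactly at
#' every age. All rates are the period rates of the stated year (a synthetic
#' cohort): migration plays no role by construction.
#'
#' @param births Births frame carrying male and female birth counts for the
#'   region-year (`sex_of_child` rows, summed over maternal ages).
#' @param lifetables Life-table frame covering ages `0..max_age` for both
#'   sexes in the region-year.
#' @param region_id,year Region and period year.
#' @param max_age Highest age to decompose.
#' @param scale `100` (men per 100 women, default) or `1`.
#' @return A tibble with one row per age `0..max_age`: `sr_total`,
#'   `birth_contribution` (constant over ages), `mortality_contribution`
#'   (cumulative survivorship ratio), and `survival_ratio_increment`
#'   (`p_m(x) / p_w(x)`, the per-age factor, for bar-style displays).
#' @export
#' @examples
#' lt <- tibble::tibble(region_id = "R", year = 2000,
#'                      sex = rep(c("male", "female"), each = 3),
#'                      age = rep(0:2, 2), p = c(rep(0.99, 3), rep(1, 3)))
#' b <- tibble::tibble(region_id = "R", year = 2000,
#'                     sex_of_child = c("male", "female"),
#'                     mother_age = "all", count = c(100, 100))
#' decompose_sex_ratio(b, lt, "R", 2000, max_age = 2)
decompose_sex_ratio <- function(births, lifetables, region_id, year,
                                max_age = 100L, scale = 100) {
  stopifnot(scale %in% c(1, 100))
  bsub <- births[births$region_id == region_id & births$year == year &
                   births$sex_of_child %in% c("male", "female"), ]
  if (nrow(bsub) == 0) {
    stop("missing-data error: no sex-specific births for ", region_id, "/",
         year, call. = FALSE)
  }
  b_m <- sum(bsub$count[bsub$sex_of_child == "male"])
  b_w <- sum(bsub$count[bsub$sex_of_child == "female"])
  if (b_w <= 0) {
    stop("domain error: female births are zero for ", region_id, "/", year,
         call. = FALSE)
  }
  ages <- 0:max_age
  get_p <- function(sex) {
    sub <- lifetables[lifetables$region_id == region_id &
                        lifetables$year == year & lifetables$sex == sex, ]
    p <- sub$p[match(ages, sub$age)]
    if (any(is.na(p))) {
      stop("missing-data error: ", sex, " life table lacks age(s) ",
           paste(ages[is.na(p)], collapse = ", "), " for ", region_id, "/",
           year, call. = FALSE)
    }
    p
  }
  p_m <- get_p("male")
  p_w <- get_p("female")
  # survivorship from birth to exact age x: empty product at x = 0
  surv_m <- cumprod(c(1, p_m[-length(p_m)]))
  surv_w <- cumprod(c(1, p_w[-length(p_w)]))
  birth_contribution <- scale * b_m / b_w
  mortality_contribution <- surv_m / surv_w
  tibble::tibble(region_id = region_id, year = as.integer(year), age = ages,
                 sr_total = birth_contribution * mortality_contribution,
                 birth_contribution = birth_contribution,
                 mortality_contribution = mortality_contribution,
                 survival_ratio_increment = p_m / p_w)
}

#' Age at which women start to outnumber men
#'
#' Smallest age whose synthetic-cohort sex ratio falls strictly below parity
#' (100 men per 100 women on the default scale); `NA` if it never does.
#'
#' @param decomposition Output of [decompose_sex_ratio()] (contiguous ages).
#' @param parity Parity level matching the decomposition's scale: 100
#'   (default) for men-per-100-women, 1 for plain ratios.
#' @return Integer age, or `NA_integer_` when the ratio never drops below
#'   parity.
#' @export
crossover_age <- function(decomposition, parity = 100) {
  stopifnot(all(diff(decomposition$age) == 1))
  below <- which(decomposition$sr_total < parity)
  if (length(below) == 0) NA_integer_ else decomposition$age[below[1]]
}
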