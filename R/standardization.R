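# Births by single maternal age for one region-year: prefer sex_of_child ==
# "all" rows; otherwise sum male + female by age.
.births_by_mother_age <- function(births, region_id, year) {
  sub <- births[births$region_id == region_id & births$year == year &
                  births$mother_age != "all", ]
  if (nrow(sub) == 0) return(NULL)
  if (any(sub$sex_of_child == "all")) {
    sub <- sub[sub$sex_of_child == "all", ]
  }
  agg <- dplyr::summarise(dplyr::group_by(sub, age = as.integer(.data$mother_age)),
                          count = sum(.data$count), .groups = "drop")
  agg
}

#' Standardized male TFR for one region-year
#'
#' The male TFR that would obtain if men experienced the women's observed
#' fertility schedule: births by maternal age are divided by the male
#' population at the same ages and summed over the reproductive range,
#' `tfr_std = sum_x B_x / P_x^male`. Comparing it to the female TFR computed
#' from the same inputs (`sum_x B_x / P_x^female`) isolates the pure
#' sex-ratio effect, since the schedule is identical by construction.
#'
#' @param births Births frame with single maternal ages for the region-year.
#' @param pop Population frame.
#' @param region_id,year Region and year to evaluate.
#' @param age_range Inclusive maternal/paternal age range; default 15--55.
#' @return A one-row tibble with `region_id`, `year`, `tfr_std`,
#'   `tfr_female`, `ratio_std` (= `tfr_std / tfr_female`, `NA` when
#'   `tfr_female` is 0).
#' @export
#' @examples
#' births <- tibble::tibble(region_id = "R", year = 2000, sex_of_child = "all",
#'                          mother_age = c("25", "30"), count = c(80, 120))
#' pop <- tibble::tibble(region_id = "R", year = 2000,
#'                       age = rep(c(25, 30), 2),
#'                       sex = rep(c("male", "female"), each = 2),
#'                       count = c(1000, 800, 1000, 800))
#' standardize_tfr(births, pop, "R", 2000) # tfr_std = 80/1000 + 120/800 = 0.23
standardize_tfr <- function(births, pop, region_id, year,
                            age_range = c(15L, 55L)) {
  bx <- .births_by_mother_age(births, region_id, year)
  if (is.null(bx)) {
    stop("missing-data error: no births by maternal age for ", region_id, "/",
         year, call. = FALSE)
  }
  bx <- bx[bx$age >= age_range[1] & bx$age <= age_range[2], ]
  sub <- pop[pop$region_id == region_id & pop$year == year, ]
  rate_sum <- function(sex) {
    p <- sub[sub$sex == sex, ]
    pmatch_count <- p$count[match(bx$age, p$age)]
    active <- bx$count > 0
    if (any(active & (is.na(pmatch_count) | pmatch_count <= 0))) {
      bad <- bx$age[active & (is.na(pmatch_count) | pmatch_count <= 0)]
      stop("domain error: births at age(s) ", paste(bad, collapse = ", "),
           " with zero ", sex, " population (", region_id, "/", year, ")",
           call. = FALSE)
    }
    # ages with B_x = 0 contribute 0 regardless of population
    sum(ifelse(active, bx$count / pmatch_count, 0))
  }
  tfr_std <- rate_sum("male")
  tfr_female <- rate_sum("female")
  tibble::tibble(region_id = region_id, year = as.integer(year),
                 tfr_std = tfr_std, tfr_female = tfr_female,
                 ratio_std = ifelse(tfr_female > 0, tfr_std / tfr_female,
                                    NA_real_))
}

#' Standardized male TFRs across a panel
#'
#' Vectorized [standardize_tfr()] over region-years. Region-years that fail
#' (missing births or zero male exposure at an age with births) are skipped
#' and reported in the `skipped` attribute.
#'
#' @inheritParams standardize_tfr
#' @param regions,years Regions and years to evaluate; defaults to all
#'   combinations present in `births`.
#' @return A tibble of per region-year standardized TFRs with a `skipped`
#'   attribute listing failures.
#' @export
standardize_panel <- function(births, pop, regions = NULL, years = NULL,
                              age_range = c(15L, 55L)) {
  if (is.null(regions)) regions <- unique(births$region_id)
  if (is.null(years)) years <- sort(unique(births$year))
  rows <- list()
  skipped <- character(0)
  for (r in regions) {
    for (y in years) {
      res <- tryCatch(standardize_tfr(births, pop, r, y, age_range),
                      error = function(e) conditionMessage(e))
      if (is.character(res)) {
        skipped <- c(skipped, paste0(r, "/", y, ": ", res))
      } else {
        rows[[length(rows) + 1]] <- res
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "skipped") <- skipped
  out
}
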