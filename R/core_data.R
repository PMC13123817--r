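#' @importFrom rlang .data
#' @importFrom stats rnorm qt coef vcov setNames
#' @importFrom utils read.csv write.csv
NULL

# Column schemas for the four long-format interchange tables. One record type
# per CSV file, UTF-8, period decimal separator; column order is fixed and
# documented here so that write_frame() output is stable.
.frame_schemas <- list(
  population = c("region_id", "year", "age", "sex", "count"),
  births     = c("region_id", "year", "sex_of_child", "mother_age", "count"),
  lifetable  = c("region_id", "year", "sex", "age", "p"),
  fertility  = c("region_id", "year", "tfr_female", "tfr_male")
)

.sex_levels <- c("male", "female")

#' Validate a demographic frame against its schema and invariants
#'
#' Checks the type-specific invariants of the four interchange tables:
#' population counts and birth counts must be non-negative, ages must lie in
#' plausible ranges (0--110 for population, 10--60 or `"all"` for maternal
#' age), survival probabilities must lie in \[0, 1\] with contiguous ages per
#' region-year-sex, and key columns must be unique. Where a births table
#' contains both single-age rows and an `"all"` total for the same
#' region-year-sex, the total must match the sum of the single ages to a
#' relative tolerance of 1e-9.
#'
#' @param frame A data frame with the columns of the given `table_kind`.
#' @param table_kind One of `"population"`, `"births"`, `"lifetable"`,
#'   `"fertility"`.
#' @return The validated frame as a tibble, invisibly usable downstream.
#' @export
validate_frame <- function(frame, table_kind = c("population", "births",
                                                 "lifetable", "fertility")) {
  table_kind <- match.arg(table_kind)
  schema <- .frame_schemas[[table_kind]]
  if (table_kind == "fertility" && !("tfr_male" %in% names(frame))) {
    frame$tfr_male <- NA_real_  # optional: present only for training/validation
  }
  missing_cols <- setdiff(schema, names(frame))
  if (length(missing_cols) > 0) {
    stop("schema error: missing column(s) ", paste(missing_cols, collapse = ", "),
         " for table kind '", table_kind, "'", call. = FALSE)
  }
  frame <- tibble::as_tibble(frame)[schema]

  fail <- function(rows, rule) {
    stop("validation error in ", table_kind, " frame, row(s) ",
         paste(utils::head(rows, 10), collapse = ", "), ": ", rule,
         call. = FALSE)
  }
  check_unique <- function(keys) {
    dup <- which(duplicated(keys))
    if (length(dup) > 0) fail(dup, "duplicate key")
  }

  if (table_kind == "population") {
    frame$year <- as.integer(frame$year)
    frame$age <- as.integer(frame$age)
    frame$count <- as.numeric(frame$count)
    bad <- which(!(frame$sex %in% .sex_levels))
    if (length(bad) > 0) fail(bad, "sex must be 'male' or 'female'")
    bad <- which(!is.finite(frame$count) | frame$count < 0)
    if (length(bad) > 0) fail(bad, "count must be a non-negative number")
    bad <- which(is.na(frame$age) | frame$age < 0 | frame$age > 110)
    if (length(bad) > 0) fail(bad, "age must be in [0, 110]")
    check_unique(frame[c("region_id", "year", "age", "sex")])
  } else if (table_kind == "births") {
    frame$year <- as.integer(frame$year)
    frame$count <- as.numeric(frame$count)
    frame$mother_age <- as.character(frame$mother_age)
    frame$sex_of_child <- as.character(frame$sex_of_child)
    bad <- which(!(frame$sex_of_child %in% c(.sex_levels, "all")))
    if (length(bad) > 0) fail(bad, "sex_of_child must be 'male', 'female' or 'all'")
    bad <- which(!is.finite(frame$count) | frame$count < 0)
    if (length(bad) > 0) fail(bad, "count must be a non-negative number")
    age_num <- suppressWarnings(as.numeric(frame$mother_age))
    is_all <- frame$mother_age == "all"
    bad <- which(!is_all & (is.na(age_num) | age_num < 10 | age_num > 60 |
                              age_num != floor(age_num)))
    if (length(bad) > 0) fail(bad, "mother_age must be an integer in [10, 60] or 'all'")
    check_unique(frame[c("region_id", "year", "sex_of_child", "mother_age")])
    # 'all' maternal-age totals must agree with the single-age sum when both exist
    by_age <- frame[!is_all, ]
    totals <- frame[is_all, ]
    if (nrow(by_age) > 0 && nrow(totals) > 0) {
      sums <- dplyr::summarise(
        dplyr::group_by(by_age, .data$region_id, .data$year, .data$sex_of_child),
        .sum = sum(.data$count), .groups = "drop")
      joined <- dplyr::inner_join(
        totals, sums, by = c("region_id", "year", "sex_of_child"))
      off <- abs(joined$count - joined$.sum) >
        1e-9 * pmax(abs(joined$count), abs(joined$.sum), 1e-300)
      if (any(off)) {
        fail(which(off), "'all' maternal-age total inconsistent with single-age sum")
      }
    }
  } else if (table_kind == "lifetable") {
    frame$year <- as.integer(frame$year)
    frame$age <- as.integer(frame$age)
    frame$p <- as.numeric(frame$p)
    bad <- which(!(frame$sex %in% .sex_levels))
    if (length(bad) > 0) fail(bad, "sex must be 'male' or 'female'")
    bad <- which(!is.finite(frame$p) | frame$p < 0 | frame$p > 1)
    if (length(bad) > 0) fail(bad, "p must be a probability in [0, 1]")
    check_unique(frame[c("region_id", "year", "sex", "age")])
    gaps <- dplyr::summarise(
      dplyr::group_by(frame, .data$region_id, .data$year, .data$sex),
      .ok = identical(sort(.data$age), seq(0L, max(.data$age))),
      .groups = "drop")
    if (any(!gaps$.ok)) {
      bad_grp <- gaps[!gaps$.ok, ]
      fail(seq_len(nrow(bad_grp)),
           paste0("ages must be contiguous from 0 (", bad_grp$region_id[1],
                  "/", bad_grp$year[1], "/", bad_grp$sex[1], ")"))
    }
  } else { # fertility
    frame$year <- as.integer(frame$year)
    frame$tfr_female <- as.numeric(frame$tfr_female)
    frame$tfr_male <- as.numeric(frame$tfr_male)
    bad <- which(!is.finite(frame$tfr_female) | frame$tfr_female < 0)
    if (length(bad) > 0) fail(bad, "tfr_female must be a non-negative number")
    bad <- which(!is.na(frame$tfr_male) & frame$tfr_male < 0)
    if (length(bad) > 0) fail(bad, "tfr_male must be non-negative when present")
    check_unique(frame[c("region_id", "year")])
  }
  frame
}

#' Read a demographic frame from CSV
#'
#' Reads one of the four interchange tables (`population.csv`, `births.csv`,
#' `lifetable.csv`, `fertility.csv` schemas) and validates every row against
#' the type's invariants. Row order is preserved.
#'
#' @inheritParams validate_frame
#' @param path Path to a CSV file with a header row.
#' @return A validated tibble.
#' @export
#' @examples
#' path <- tempfile(fileext = ".csv")
#' writeLines(c("region_id,year,age,sex,count", "R1,2000,25,male,1000"), path)
#' read_frame(path, "population")
read_frame <- function(path, table_kind = c("population", "births",
                                            "lifetable", "fertility")) {
  table_kind <- match.arg(table_kind)
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  schema <- .frame_schemas[[table_kind]]
  if (table_kind == "fertility" && !("tfr_male" %in% names(raw))) {
    raw$tfr_male <- NA_character_
  }
  missing_cols <- setdiff(schema, names(raw))
  if (length(missing_cols) > 0) {
    stop("schema error: missing column(s) ", paste(missing_cols, collapse = ", "),
         " in ", path, call. = FALSE)
  }
  raw <- raw[schema]
  numeric_cols <- setdiff(schema, c("region_id", "sex", "sex_of_child",
                                    "mother_age", "tfr_male"))
  for (col in numeric_cols) raw[[col]] <- as.numeric(raw[[col]])
  if (table_kind == "fertility") {
    raw$tfr_male <- suppressWarnings(as.numeric(raw$tfr_male))
  }
  validate_frame(raw, table_kind)
}

#' Write a demographic frame to CSV
#'
#' Writes the frame with the stable documented column order so that
#' `read_frame(write_frame(x))` round-trips exactly (numbers are serialized
#' with full round-trip precision).
#'
#' @inheritParams validate_frame
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frame <- function(frame, path, table_kind = c("population", "births",
                                                    "lifetable", "fertility")) {
  table_kind <- match.arg(table_kind)
  frame <- validate_frame(frame, table_kind)
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    stop("I/O error: directory does not exist: ", dir, call. = FALSE)
  }
  out <- frame
  for (col in names(out)) {
    # 17 significant digits: doubles survive the CSV exactly
    if (is.double(out[[col]])) {
      txt <- sprintf("%.17g", out[[col]])
      txt[is.na(out[[col]])] <- "NA"
      out[[col]] <- txt
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Adult (reproductive-age) sex ratio
#'
#' Ratio of the male population summed over `male_ages` to the female
#' population summed over `female_ages` for one region-year. Ages are
#' completed years and both ranges are inclusive of their endpoints, so
#' `c(20, 39)` means ages 20 through 39. This is the regressor SR of the
#' male-TFR model; the age-gap variant uses men 25--44 over women 20--39.
#'
#' @param pop A validated population frame.
#' @param region_id,year Region and calendar year to evaluate.
#' @param male_ages,female_ages Length-2 integer vectors, inclusive age ranges.
#' @return A positive scalar, male/female population ratio.
#' @export
#' @examples
#' pop <- tibble::tibble(
#'   region_id = "R1", year = 2000,
#'   age = rep(20:39, 2), sex = rep(c("male", "female"), each = 20),
#'   count = c(rep(55, 20), rep(50, 20)))
#' adult_sex_ratio(pop, "R1", 2000, c(20, 39), c(20, 39)) # 1.1
adult_sex_ratio <- function(pop, region_id, year, male_ages = c(20L, 39L),
                            female_ages = c(20L, 39L)) {
  stopifnot(length(male_ages) == 2, length(female_ages) == 2,
            male_ages[1] <= male_ages[2], female_ages[1] <= female_ages[2])
  sub <- pop[pop$region_id == region_id & pop$year == year, ]
  sum_side <- function(sex, ages) {
    want <- seq(ages[1], ages[2])
    rows <- sub[sub$sex == sex & sub$age %in% want, ]
    missing_ages <- setdiff(want, rows$age)
    if (length(missing_ages) > 0) {
      stop("missing-data error: no ", sex, " population for ", region_id, "/",
           year, " at age(s) ", paste(missing_ages, collapse = ", "),
           call. = FALSE)
    }
    sum(rows$count)
  }
  males <- sum_side("male", male_ages)
  females <- sum_side("female", female_ages)
  if (females <= 0) {
    stop("domain error: female population is zero for ", region_id, "/", year,
         call. = FALSE)
  }
  males / females
}

#' Split 5-year grouped births uniformly into single ages
#'
#' Helper for births tables reported by 5-year maternal age group (identified
#' by rows like `"15-19"` in `mother_age`): each group's count is divided
#' equally across its single ages. Single-age and `"all"` rows pass through
#' unchanged.
#'
#' @param births A births frame whose `mother_age` may contain `"lo-hi"` groups.
#' @return A births tibble with single-age `mother_age` values.
#' @export
split_grouped_births <- function(births) {
  grouped <- grepl("^[0-9]+-[0-9]+$", births$mother_age)
  if (!any(grouped)) return(validate_frame(births, "births"))
  keep <- births[!grouped, ]
  expand_one <- function(row) {
    bounds <- as.integer(strsplit(row$mother_age, "-", fixed = TRUE)[[1]])
    ages <- seq(bounds[1], bounds[2])
    tibble::tibble(region_id = row$region_id, year = row$year,
                   sex_of_child = row$sex_of_child,
                   mother_age = as.character(ages),
                   count = row$count / length(ages))
  }
  pieces <- lapply(which(grouped), function(i) expand_one(births[i, ]))
  out <- dplyr::bind_rows(keep, pieces)
  validate_frame(out, "births")
}
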