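#' Pipeline configuration
#'
#' Assembles the run configuration for [run_pipeline()]. Provide either a
#' `scenario` ([scenario_config()] or a list of its arguments) to simulate
#' the inputs, or `inputs`, a named list of paths to the four interchange
#' CSVs (`population`, `births`, `lifetable`, `fertility`). Every numeric
#' default the analysis depends on (model variant and its age ranges,
#' interval level, standardization age range, crossover threshold) is
#' surfaced here rather than hard-coded.
#'
#' @param scenario Optional scenario specification for simulated inputs.
#' @param inputs Optional named list of CSV paths for observed inputs.
#' @param training Optional path to a fertility CSV with observed `tfr_male`
#'   plus a matching `sex_ratio` column, used to fit the regression. When
#'   absent and the input fertility table carries no observed male TFRs, the
#'   shipped coefficient set for `variant` is used (points only, no
#'   intervals).
#' @param variant Model variant name; default `"age_gap"`.
#' @param pi_level Prediction-interval level in (0, 1).
#' @param std_age_range Inclusive age range for standardization.
#' @param decompose_max_age Highest age in the sex-ratio decomposition.
#' @param threshold Percent threshold for the population-weighted share.
#' @param out_dir Output directory.
#' @param seed Integer seed recorded in the manifest and forwarded to the
#'   scenario generator.
#' @param log_level `"info"` (stage messages with row counts) or `"quiet"`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(scenario = NULL, inputs = NULL, training = NULL,
                            variant = "age_gap", pi_level = 0.90,
                            std_age_range = c(15L, 55L),
                            decompose_max_age = 100L, threshold = 5,
                            out_dir = "malefert-run", seed = 1L,
                            log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  if (is.null(scenario) && is.null(inputs)) {
    stop("config error: provide either a scenario or input paths", call. = FALSE)
  }
  if (!is.null(inputs)) {
    need <- c("population", "births", "lifetable", "fertility")
    missing_in <- setdiff(need, names(inputs))
    if (length(missing_in) > 0) {
      stop("config error: inputs must name ", paste(missing_in, collapse = ", "),
           call. = FALSE)
    }
    for (p in unlist(inputs)) {
      if (!file.exists(p)) stop("config error: input file not found: ", p,
                                call. = FALSE)
    }
  }
  stopifnot(pi_level > 0, pi_level < 1)
  structure(list(scenario = scenario, inputs = inputs, training = training,
                 variant = variant, pi_level = pi_level,
                 std_age_range = std_age_range,
                 decompose_max_age = as.integer(decompose_max_age),
                 threshold = threshold, out_dir = out_dir,
                 seed = as.integer(seed), log_level = log_level),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Thin wrapper mapping a YAML document onto [pipeline_config()]; the keys
#' are the constructor's argument names, with `scenario` holding
#' [scenario_config()] arguments.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config error: file not found: ", path,
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$scenario)) {
    raw$scenario <- do.call(scenario_config, raw$scenario)
  }
  do.call(pipeline_config, raw)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order — simulate (or read), fit,
#' estimate, standardize, decompose, crossover — writing each stage's output
#' CSV into `config$out_dir` together with a JSON manifest (package version,
#' seed, input checksums, per-stage row counts and skip reports). Identical
#' configuration and seed produce byte-identical numeric outputs.
#'
#' @param config A [pipeline_config()] or path to a YAML file for
#'   [read_pipeline_config()].
#' @return The manifest, invisibly, with the stage outputs attached as
#'   `attr(, "results")`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (config$log_level == "info") message("[malefert] ", ...)
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  manifest <- list(package = "malefert",
                   version = as.character(utils::packageVersion("malefert")),
                   seed = config$seed, variant = config$variant,
                   stages = list())

  # -- stage: simulate or read ------------------------------------------------
  if (!is.null(config$scenario)) {
    sc <- config$scenario
    if (!inherits(sc, "scenario_config")) {
      sc$seed <- config$seed
      sc <- do.call(scenario_config, sc)
    }
    frames <- generate_scenario(sc)
    in_dir <- file.path(out_dir, "inputs")
    write_scenario(frames, in_dir)
    input_paths <- c(population = file.path(in_dir, "population.csv"),
                     births = file.path(in_dir, "births.csv"),
                     lifetable = file.path(in_dir, "lifetable.csv"),
                     fertility = file.path(in_dir, "fertility.csv"))
    say("simulate: wrote scenario inputs to ", in_dir)
  } else {
    input_paths <- unlist(config$inputs)
    frames <- list(population = read_frame(input_paths[["population"]], "population"),
                   births = read_frame(input_paths[["births"]], "births"),
                   lifetable = read_frame(input_paths[["lifetable"]], "lifetable"),
                   fertility = read_frame(input_paths[["fertility"]], "fertility"))
    say("read: loaded ", length(input_paths), " input tables")
  }
  manifest$inputs <- as.list(tools::md5sum(unname(input_paths)))
  manifest$stages$inputs <- lapply(
    frames[c("population", "births", "lifetable", "fertility")], nrow)

  # -- stage: fit -------------------------------------------------------------
  if (!is.null(config$training)) {
    training <- utils::read.csv(config$training)
    fit <- fit_male_tfr(training, config$variant)
    say("fit: OLS on ", fit$n_obs, " training observations, R2 = ",
        signif(fit$r_squared, 4))
  } else if (any(!is.na(frames$fertility$tfr_male))) {
    obs <- frames$fertility[!is.na(frames$fertility$tfr_male), ]
    v <- model_variant(config$variant)
    obs$sex_ratio <- vapply(seq_len(nrow(obs)), function(i)
      adult_sex_ratio(frames$population, obs$region_id[i], obs$year[i],
                      v$male_ages, v$female_ages), numeric(1))
    fit <- fit_male_tfr(obs, config$variant)
    say("fit: OLS on ", fit$n_obs, " observed country-years")
  } else {
    fit <- male_tfr_fit_from_coefficients(default_coefficients(config$variant),
                                          config$variant)
    say("fit: no observed male TFRs; using shipped ", config$variant,
        " coefficients (no intervals)")
  }
  manifest$stages$fit <- list(
    variant = config$variant,
    coefficients = as.list(fit$coefficients),
    n_obs = if (is.na(fit$n_obs)) NULL else fit$n_obs)

  # -- stage: estimate --------------------------------------------------------
  estimated <- estimate_panel(frames$population, frames$fertility, fit,
                              config$pi_level)
  est_path <- file.path(out_dir, "estimated.csv")
  utils::write.csv(estimated, est_path, row.names = FALSE, quote = FALSE)
  manifest$stages$estimate <- list(rows = nrow(estimated),
                                   skipped = attr(estimated, "skipped"))
  say("estimate: ", nrow(estimated), " region-years (",
      length(attr(estimated, "skipped")), " skipped)")

  # -- stage: standardize -----------------------------------------------------
  standardized <- standardize_panel(frames$births, frames$population,
                                    age_range = config$std_age_range)
  std_path <- file.path(out_dir, "standardized.csv")
  utils::write.csv(standardized, std_path, row.names = FALSE, quote = FALSE)
  manifest$stages$standardize <- list(rows = nrow(standardized),
                                      skipped = attr(standardized, "skipped"))
  say("standardize: ", nrow(standardized), " region-years")

  # -- stage: decompose -------------------------------------------------------
  keys <- unique(frames$lifetable[c("region_id", "year")])
  dec_rows <- list()
  dec_skipped <- character(0)
  for (i in seq_len(nrow(keys))) {
    res <- tryCatch(
      decompose_sex_ratio(frames$births, frames$lifetable, keys$region_id[i],
                          keys$year[i], config$decompose_max_age),
      error = function(e) conditionMessage(e))
    if (is.character(res)) {
      dec_skipped <- c(dec_skipped,
                       paste0(keys$region_id[i], "/", keys$year[i], ": ", res))
    } else {
      dec_rows[[length(dec_rows) + 1]] <- res
    }
  }
  decomposition <- dplyr::bind_rows(dec_rows)
  dec_path <- file.path(out_dir, "decomposition.csv")
  utils::write.csv(decomposition, dec_path, row.names = FALSE, quote = FALSE)
  manifest$stages$decompose <- list(rows = nrow(decomposition),
                                    skipped = dec_skipped)
  say("decompose: ", nrow(decomposition), " region-year-ages")

  # -- stage: crossover -------------------------------------------------------
  xo_rows <- list()
  for (r in unique(estimated$region_id)) {
    sub <- estimated[estimated$region_id == r & !is.na(estimated$tfr_male), ]
    sub <- sub[order(sub$year), ]
    if (nrow(sub) == 0) next
    res <- crossover_result(sub, r)
    xo_rows[[length(xo_rows) + 1]] <- tibble::tibble(
      region_id = r, year = res$pct_diff_series$year,
      pct_diff = res$pct_diff_series$pct_diff,
      crossover_year = res$crossover_year,
      min_pct_diff_year = res$min_pct_diff_year)
  }
  crossover_tbl <- dplyr::bind_rows(xo_rows)
  xo_path <- file.path(out_dir, "crossover.csv")
  utils::write.csv(crossover_tbl, xo_path, row.names = FALSE, quote = FALSE)

  pop_totals <- dplyr::summarise(
    dplyr::group_by(frames$population, .data$region_id, .data$year),
    population = sum(.data$count), .groups = "drop")
  shares <- share_summary(estimated[!is.na(estimated$tfr_male), ], pop_totals,
                          config$threshold)
  shares_path <- file.path(out_dir, "shares.csv")
  utils::write.csv(shares, shares_path, row.names = FALSE, quote = FALSE)
  manifest$stages$crossover <- list(rows = nrow(crossover_tbl),
                                    share_rows = nrow(shares))
  say("crossover: ", length(xo_rows), " regions, ", nrow(shares),
      " yearly share summaries")

  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  say("manifest: ", manifest_path)

  results <- list(fit = fit, estimated = estimated,
                  standardized = standardized, decomposition = decomposition,
                  crossover = crossover_tbl, shares = shares)
  attr(manifest, "results") <- results
  invisible(manifest)
}
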