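#' Percent-difference trend lines
#'
#' Line chart of the per-year percent difference between male and female TFR
#' by region, with the zero equilibrium line and a dashed vertical marker at
#' each region's crossover year.
#'
#' @param crossover_tbl Tibble as written by the pipeline's crossover stage
#'   (`region_id`, `year`, `pct_diff`, `crossover_year`).
#' @return A ggplot object.
#' @export
plot_percent_difference <- function(crossover_tbl) {
  marks <- unique(crossover_tbl[!is.na(crossover_tbl$crossover_year),
                                c("region_id", "crossover_year")])
  p <- ggplot2::ggplot(crossover_tbl,
                       ggplot2::aes(x = .data$year, y = .data$pct_diff,
                                    colour = .data$region_id)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Year", y = "TFR difference, male vs female (%)",
                  colour = "Region") +
    ggplot2::theme_minimal()
  if (nrow(marks) > 0) {
    p <- p + ggplot2::geom_vline(
      data = marks,
      ggplot2::aes(xintercept = .data$crossover_year,
                   colour = .data$region_id),
      linetype = "dashed", show.legend = FALSE)
  }
  p
}

#' Sex-ratio decomposition bars
#'
#' For selected ages, plots the birth-contribution and per-age survival-ratio
#' bars with the total synthetic-cohort sex ratio as a line over years,
#' mirroring the standard drivers-of-sex-imbalance display.
#'
#' @param decomposition Tibble of [decompose_sex_ratio()] rows across years.
#' @param ages Ages to facet; default `c(0, 25, 50)` (kept to those present).
#' @return A ggplot object.
#' @export
plot_decomposition <- function(decomposition, ages = c(0, 25, 50)) {
  ages <- intersect(ages, unique(decomposition$age))
  sub <- decomposition[decomposition$age %in% ages, ]
  scale0 <- ifelse(max(sub$birth_contribution) > 10, 100, 1)
  long <- tidyr::pivot_longer(
    sub[c("region_id", "year", "age", "birth_contribution",
          "mortality_contribution")],
    cols = c("birth_contribution", "mortality_contribution"),
    names_to = "component", values_to = "value")
  long$value <- ifelse(long$component == "birth_contribution",
                       long$value / scale0, long$value)
  ggplot2::ggplot(sub, ggplot2::aes(x = .data$year)) +
    ggplot2::geom_col(data = long,
                      ggplot2::aes(y = .data$value, fill = .data$component),
                      position = "dodge", alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$sr_total / scale0)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$sr_total / scale0), size = 0.8) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$age),
                        cols = ggplot2::vars(.data$region_id)) +
    ggplot2::labs(x = "Year", y = "Sex ratio (1 = parity)", fill = NULL) +
    ggplot2::theme_minimal()
}
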