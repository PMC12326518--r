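#' Station-by-hour matrices of proximity and normalised detection rate
#'
#' Builds the two heat-map style matrices used to eyeball the spatial
#' pattern of calling: the proximity category of the fish mass to each
#' station per hour, and the effort-normalised detection rate per station
#' and hour. Station rows, hour columns; hours absent from the data are
#' `NA`.
#'
#' @param hourcells Hour-cell tibble with `station_id`, `hour_start`,
#'   `rate` and (optionally) `FP_index`.
#' @return A list of matrices `rate` and (if `FP_index` present)
#'   `proximity`.
#' @export
report_heatmaps <- function(hourcells) {
  if (nrow(hourcells) == 0) abort("`hourcells` is empty")
  to_mat <- function(col) {
    wide <- hourcells %>%
      select("station_id", "hour_start", dplyr::all_of(col)) %>%
      mutate(hour = format_iso(.data$hour_start)) %>%
      select(-"hour_start") %>%
      tidyr::pivot_wider(names_from = "hour", values_from = dplyr::all_of(col))
    m <- as.matrix(wide[, -1])
    rownames(m) <- wide$station_id
    m[, order(colnames(m)), drop = FALSE]
  }
  out <- list(rate = to_mat("rate"))
  if ("FP_index" %in% names(hourcells)) out$proximity <- to_mat("FP_index")
  out
}

#' Box-plot summary tables of detection rates by hour of day and by DAFS
#'
#' Summarises the effort-normalised rates per station and category (hour of
#' day 0-23, or day after first spawn -4..+2) with the median, quartiles
#' (linear-interpolation quantiles) and whiskers at the data points nearest
#' to 1.5 x the interquartile range — the convention used for box plots
#' throughout the package.
#'
#' @param hourcells Hour-cell tibble with `rate`, `T_index` and optionally
#'   `D_index`.
#' @return A list of tibbles `by_hour` and (if `D_index` present) `by_dafs`,
#'   each with `station_id`, the category, `median`, `q25`, `q75`,
#'   `whisker_lo`, `whisker_hi`, `n`.
#' @export
report_boxplots <- function(hourcells) {
  if (nrow(hourcells) == 0) abort("`hourcells` is empty")
  summarize_by <- function(col, out_col) {
    hourcells %>%
      group_by(.data$station_id, value = .data[[col]]) %>%
      summarise(bp = list(boxplot_summary(.data$rate)),
                n = dplyr::n(), .groups = "drop") %>%
      tidyr::unnest("bp") %>%
      rename(!!out_col := "value")
  }
  out <- list(by_hour = summarize_by("T_index", "hour_of_day"))
  if ("D_index" %in% names(hourcells)) {
    out$by_dafs <- summarize_by("D_index", "D_index") %>%
      mutate(dafs = .data$D_index - 4L, .after = "D_index")
  }
  out
}

#' Heat map of effort-normalised rates (and proximity) per station and hour
#'
#' @param hourcells Hour-cell tibble.
#' @return A ggplot object: tiles of `rate` by hour (x) and station (y).
#' @export
plot_rate_heatmap <- function(hourcells) {
  ggplot2::ggplot(hourcells,
                  ggplot2::aes(x = .data$hour_start, y = .data$station_id,
                               fill = .data$rate)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "calls / h") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Box plots of detection rate by hour of day
#'
#' @param hourcells Hour-cell tibble with `rate` and `T_index`.
#' @return A ggplot object, one panel per station.
#' @export
plot_hourly_boxplots <- function(hourcells) {
  bp <- report_boxplots(hourcells)$by_hour
  ggplot2::ggplot(bp, ggplot2::aes(x = factor(.data$hour_of_day))) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$whisker_lo,
                                        ymax = .data$whisker_hi), width = 0.3) +
    ggplot2::geom_crossbar(ggplot2::aes(y = .data$median, ymin = .data$q25,
                                        ymax = .data$q75), fill = "grey85") +
    ggplot2::facet_wrap(~station_id, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "hour of day", y = "effort-normalised calls / h") +
    ggplot2::theme_minimal()
}
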