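#' Posterior summaries of the category effects on the rate scale
#'
#' Exponentiates each draw of the hour-of-day (`T`), day-after-first-spawn
#' (`D`) and proximity (`FP`) effects and summarises them per category with
#' the posterior median and quartiles (plus 1.5-IQR whisker bounds for
#' box-plot style displays). Because every category carries its own prior
#' and there is no reference level, absolute levels trade off additively
#' between the three factors; within-factor comparisons (e.g. evening vs
#' morning hours) are the meaningful contrasts.
#'
#' @param fit An `aas_fit`.
#' @return A tibble with columns `factor` (`"T"`, `"D"`, `"FP"`), `level`
#'   (hour 0-23, DAFS -4..2, or proximity 0-2), `median`, `q25`, `q75`,
#'   `whisker_lo`, `whisker_hi` on the multiplicative rate scale.
#' @export
predict_effects <- function(fit) {
  stopifnot(inherits(fit, "aas_fit"))
  specs <- list(
    list(factor = "T", cols = sprintf("T[%d]", 1:24), level = 0:23),
    list(factor = "D", cols = sprintf("D[%d]", 1:7), level = -4:2),
    list(factor = "FP", cols = sprintf("FP[%d]", 1:3), level = 0:2)
  )
  purrr::map_dfr(specs, function(s) {
    purrr::map_dfr(seq_along(s$cols), function(k) {
      v <- exp(fit$draws[, s$cols[k]])
      bp <- boxplot_summary(v)
      tibble(factor = s$factor, level = s$level[k]) %>% dplyr::bind_cols(bp)
    })
  })
}

# quartiles by linear interpolation (type 7) and whiskers at the data points
# nearest to 1.5 x IQR beyond the quartiles
boxplot_summary <- function(v) {
  q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  lo_lim <- q[1] - 1.5 * iqr
  hi_lim <- q[3] + 1.5 * iqr
  inside <- v[v >= lo_lim & v <= hi_lim]
  tibble(median = q[2], q25 = q[1], q75 = q[3],
         whisker_lo = if (length(inside)) min(inside) else q[1],
         whisker_hi = if (length(inside)) max(inside) else q[3])
}

#' Box-plot display of the posterior category effects
#'
#' @param object An `aas_fit`.
#' @param ... Unused.
#' @return A ggplot with one panel per factor showing the posterior median,
#'   interquartile box and 1.5-IQR whiskers of each category effect on the
#'   rate scale.
#' @exportS3Method ggplot2::autoplot
autoplot.aas_fit <- function(object, ...) {
  eff <- predict_effects(object)
  ggplot2::ggplot(eff, ggplot2::aes(x = factor(.data$level))) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$whisker_lo, ymax = .data$whisker_hi),
      width = 0.3) +
    ggplot2::geom_crossbar(
      ggplot2::aes(y = .data$median, ymin = .data$q25, ymax = .data$q75),
      fill = "grey85") +
    ggplot2::facet_wrap(~factor, scales = "free", ncol = 1) +
    ggplot2::labs(x = "category", y = "multiplicative effect on call rate") +
    ggplot2::theme_minimal()
}
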