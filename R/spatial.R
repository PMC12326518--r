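#' Pairwise posterior correlation summaries joined with distance
#'
#' Extracts the posterior draws of each off-diagonal entry of the station
#' correlation matrix and summarises them (median, 25% and 75% quantiles),
#' joining each pair with its great-circle distance. With `J` stations the
#' result has `J(J-1)/2` rows.
#'
#' @param fit An `aas_fit`.
#' @param geometry Station geometry (used to compute distances); must cover
#'   every station in the fit.
#' @return A tibble `station_a`, `station_b`, `distance_m`, `rho_median`,
#'   `rho_q25`, `rho_q75`.
#' @export
correlation_pairs <- function(fit, geometry) {
  stopifnot(inherits(fit, "aas_fit"))
  ids <- fit$design$stations
  if (!all(ids %in% geometry$station_id)) {
    abort("geometry does not cover all fitted stations")
  }
  geometry <- geometry[match(ids, geometry$station_id), ]
  dm <- haversine_matrix(geometry)
  J <- length(ids)
  pairs <- which(upper.tri(diag(J)), arr.ind = TRUE)
  purrr::map_dfr(seq_len(nrow(pairs)), function(k) {
    a <- pairs[k, "row"]; b <- pairs[k, "col"]
    v <- fit$draws[, sprintf("R[%s,%s]", ids[a], ids[b])]
    tibble(station_a = ids[a], station_b = ids[b],
           distance_m = dm[a, b],
           rho_median = median(v),
           rho_q25 = quantile(v, 0.25, names = FALSE),
           rho_q75 = quantile(v, 0.75, names = FALSE))
  }) %>%
    arrange(.data$distance_m)
}

#' Regress posterior pair correlations on inter-station distance
#'
#' Ordinary least squares of the posterior median correlation of each
#' station pair on the pair's great-circle distance, with the classical 95%
#' confidence band and the distance at which the fitted line crosses zero
#' (`-intercept / slope`). Optionally the regression is repeated for every
#' posterior draw, giving a posterior distribution of slope and crossing.
#'
#' @param pairs A pair table from [correlation_pairs()] (columns
#'   `distance_m`, `rho_median`).
#' @param fit Optional `aas_fit`; when supplied together with
#'   `draw_wise = TRUE`, per-draw regressions are summarised as well.
#' @param draw_wise Repeat the regression on each posterior draw.
#' @return An object of class `aas_corr_reg`: a list with the fitted `lm`
#'   (`model`), `slope`, `intercept`, `zero_crossing_m`, the pair table, and
#'   optionally `draw_summary`.
#' @export
corr_distance_regression <- function(pairs, fit = NULL, draw_wise = FALSE) {
  if (nrow(pairs) < 2) abort("need at least 2 pairs")
  if (length(unique(pairs$distance_m)) < 2) {
    abort("all pair distances identical; regression design is singular")
  }
  model <- lm(rho_median ~ distance_m, data = pairs)
  slope <- unname(coef(model)[2])
  intercept <- unname(coef(model)[1])
  out <- list(
    model = model,
    slope = slope,
    intercept = intercept,
    zero_crossing_m = if (slope != 0) -intercept / slope else NA_real_,
    pairs = pairs
  )
  if (draw_wise) {
    if (is.null(fit)) abort("`fit` is required for draw-wise regression")
    ids <- fit$design$stations
    cols <- sprintf("R[%s,%s]", pairs$station_a, pairs$station_b)
    d <- pairs$distance_m
    dbar <- mean(d)
    sxx <- sum((d - dbar)^2)
    slopes <- apply(fit$draws[, cols, drop = FALSE], 1, function(r) {
      sum((d - dbar) * r) / sxx
    })
    inters <- apply(fit$draws[, cols, drop = FALSE], 1, mean) - slopes * dbar
    zc <- -inters / slopes
    out$draw_summary <- tibble(
      quantity = c("slope", "intercept", "zero_crossing_m"),
      median = c(median(slopes), median(inters), median(zc)),
      q5 = c(quantile(slopes, 0.05, names = FALSE),
             quantile(inters, 0.05, names = FALSE),
             quantile(zc, 0.05, names = FALSE)),
      q95 = c(quantile(slopes, 0.95, names = FALSE),
              quantile(inters, 0.95, names = FALSE),
              quantile(zc, 0.95, names = FALSE))
    )
  }
  structure(out, class = "aas_corr_reg")
}

#' @export
print.aas_corr_reg <- function(x, ...) {
  cat("<aas_corr_reg>\n")
  cat(sprintf("  rho = %.4f %+.3g * distance_m (zero crossing %.0f m)\n",
              x$intercept, x$slope, x$zero_crossing_m))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.aas_corr_reg <- function(x, ...) {
  s <- summary(x$model)$coefficients
  tibble(term = rownames(s), estimate = unname(s[, 1]),
         std_error = unname(s[, 2]), statistic = unname(s[, 3]),
         p_value = unname(s[, 4]))
}

#' @exportS3Method generics::glance
glance.aas_corr_reg <- function(x, ...) {
  s <- summary(x$model)
  tibble(slope = x$slope, intercept = x$intercept,
         zero_crossing_m = x$zero_crossing_m,
         r_squared = s$r.squared, sigma = s$sigma,
         n_pairs = nrow(x$pairs))
}

#' Correlation-versus-distance scatter with the fitted regression line
#'
#' Plots each station pair's posterior median correlation (with 25-75%
#' quantile whiskers) against distance, the OLS line with its 95% confidence
#' band, and a dashed zero line.
#'
#' @param object An `aas_corr_reg`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.aas_corr_reg <- function(object, ...) {
  pr <- object$pairs
  grid <- tibble(distance_m = seq(min(pr$distance_m), max(pr$distance_m),
                                  length.out = 100))
  band <- as_tibble(predict(object$model, grid, interval = "confidence")) %>%
    dplyr::bind_cols(grid)
  ggplot2::ggplot(pr, ggplot2::aes(x = .data$distance_m)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_ribbon(data = band,
                         ggplot2::aes(ymin = .data$lwr, ymax = .data$upr),
                         alpha = 0.2) +
    ggplot2::geom_line(data = band, ggplot2::aes(y = .data$fit)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$rho_q25,
                                        ymax = .data$rho_q75), width = 8) +
    ggplot2::geom_point(ggplot2::aes(y = .data$rho_median), size = 2) +
    ggplot2::labs(x = "distance between stations (m)",
                  y = "posterior correlation of hourly call rates") +
    ggplot2::theme_minimal()
}
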