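#' Build the station-hour design grid for the count simulator
#'
#' Expands the observation window into one row per station and hour, attaches
#' the hour-of-day index (`T_index`, 0-23), the day-after-first-spawn index
#' (`D_index`, 0-6 for DAFS -4..+2) and the proximity category (`FP_index`),
#' and carries an effort fraction `tau`.
#'
#' @param config An [sim_config()] object.
#' @param proximity Proximity table from [simulate_fsa_trajectory()]; if
#'   `NULL` all cells get `FP_index = 0`.
#' @param tau Effort fraction(s) in (0, 1]; recycled over cells.
#' @return A design tibble with columns `station_id`, `hour_index`,
#'   `hour_start`, `tau`, `T_index`, `D_index`, `FP_index`.
#' @export
make_design <- function(config, proximity = NULL, tau = 1) {
  stopifnot(inherits(config, "aas_config"))
  hours <- parse_iso(config$start_time) + 3600 * (seq_len(config$n_hours) - 1)
  geometry <- make_geometry(config)
  grid <- tidyr::crossing(
    station_id = geometry$station_id,
    tibble(hour_index = seq_len(config$n_hours) - 1L, hour_start = hours)
  )
  start <- parse_iso(config$start_time)
  spawn0 <- as.Date(start + 3600 * config$first_spawn_hour)
  grid <- grid %>%
    mutate(
      tau = rep_len(tau, dplyr::n()),
      T_index = as.integer(format(.data$hour_start, "%H")),
      D_index = as.integer(as.Date(.data$hour_start) - spawn0) + 4L
    )
  if (any(grid$D_index < 0 | grid$D_index > 6)) {
    abort("observation window maps outside DAFS -4..+2; adjust first_spawn_hour/n_hours")
  }
  if (!is.null(proximity)) {
    grid <- grid %>%
      left_join(proximity[, c("station_id", "hour_index", "FP_index")],
                by = c("station_id", "hour_index")) %>%
      mutate(FP_index = dplyr::coalesce(.data$FP_index, 0L))
  } else {
    grid$FP_index <- 0L
  }
  arrange(grid, .data$station_id, .data$hour_index)
}

#' Simulate hourly call counts from the hierarchical Poisson process
#'
#' For each hour `i` a station random-effect vector `h[, i]` is drawn from a
#' multivariate normal with covariance `diag(sigma_h) R diag(sigma_h)`; the
#' count of each station-hour cell is then Poisson with mean
#' `tau * exp(T[T_index] + D[D_index] + FP[FP_index] + h[j, i])`. The latent
#' `h` values are returned with the cells so recovery experiments can compare
#' against the truth.
#'
#' @param params An `aas_parameters` object ([true_parameters()]).
#' @param design Design tibble from [make_design()] (columns `station_id`,
#'   `hour_index`, `tau`, `T_index`, `D_index`, `FP_index`).
#' @param seed RNG seed for this stage.
#' @return The design tibble with added columns `h` (latent random effect),
#'   `V` (simulated count) and `rate` (`V / tau`).
#' @export
simulate_hour_counts <- function(params, design, seed = 1L) {
  check_parameters(params)
  if (any(design$tau <= 0 | design$tau > 1)) {
    abort("`tau` must lie in (0, 1]; drop zero-effort cells upstream")
  }
  check_indices(design)
  stations <- sort(unique(design$station_id))
  J <- length(stations)
  if (length(params$sigma_h) != J) abort("sigma_h length != number of stations")
  # align the parameter ordering (geometry order) with the design's stations
  ord <- if (!is.null(params$station_id)) {
    m <- match(stations, params$station_id)
    if (any(is.na(m))) abort("design stations missing from `params$station_id`")
    m
  } else {
    seq_len(J)
  }
  sig <- params$sigma_h[ord]
  R <- params$R[ord, ord]
  hours <- sort(unique(design$hour_index))
  H <- length(hours)
  Sigma <- diag(sig, J) %*% R %*% diag(sig, J)
  cs <- chol_psd(Sigma)
  hmat <- with_seed(seed, {
    z <- matrix(rnorm(H * J), H, J)
    z %*% cs # rows: hours, cols: stations
  })
  dimnames(hmat) <- list(NULL, stations)
  jj <- match(design$station_id, stations)
  ii <- match(design$hour_index, hours)
  h <- hmat[cbind(ii, jj)]
  eta <- params$T[design$T_index + 1] + params$D[design$D_index + 1] +
    params$FP[design$FP_index + 1] + h
  mu <- design$tau * exp(eta)
  V <- with_seed(seed + 1, rpois(length(mu), mu))
  design %>%
    mutate(h = h, V = as.integer(V), rate = .data$V / .data$tau)
}

# upper-triangular factor usable for PSD (possibly singular) covariance
chol_psd <- function(S) {
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (!is.null(ch)) return(ch)
  ev <- eigen(S, symmetric = TRUE)
  if (min(ev$values) < -1e-8) abort("covariance is not positive semidefinite")
  t(ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), nrow(S)) %*% t(ev$vectors))
}

check_indices <- function(design) {
  with(design, {
    if (any(T_index < 0 | T_index > 23)) abort("T_index out of 0..23")
    if (any(D_index < 0 | D_index > 6)) abort("D_index out of 0..6")
    if (any(FP_index < 0 | FP_index > 2)) abort("FP_index out of 0..2")
  })
  invisible(design)
}
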