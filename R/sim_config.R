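#' Simulation configuration for the synthetic hydrophone-array dataset
#'
#' Bundles every knob of the synthetic-data generator. The defaults emulate
#' the monitoring design the package targets: a six-station linear hydrophone
#' array at 150 m spacing recording continuously over a 158-hour spawning
#' window (10:00 on day 1 through 23:00 on day 7), with hour-of-day,
#' day-after-first-spawn (DAFS) and fish-proximity effects driving a
#' Poisson-lognormal hourly call count at each station.
#'
#' @param n_stations Number of hydrophone stations (>= 1).
#' @param spacing_m Distance in metres between adjacent stations (> 0).
#' @param origin_lat,origin_lon Decimal-degree coordinates of the first
#'   station.
#' @param bearing_deg Initial bearing of the array line, degrees clockwise
#'   from north.
#' @param start_time First hour of the observation window (ISO-8601 string or
#'   POSIXct). Interpreted as local clock time; no timezone arithmetic.
#' @param n_hours Number of continuous observation hours (default 158,
#'   i.e. 10:00 day 1 through 23:00 day 7).
#' @param first_spawn_hour Zero-based index of the hour at which DAFS reaches
#'   0 (start of the first spawning day). With the default start at 10:00 and
#'   `first_spawn_hour = 86` the DAFS factor spans -4..+2 days.
#' @param T_effects 24 hour-of-day effects on the log-rate scale. The default
#'   is a crepuscular template peaking at 06:00-08:00 and 18:00-20:00, with
#'   the evening peak higher than the morning one.
#' @param D_effects 7 DAFS effects (-4..+2) on the log-rate scale; default
#'   rises to a plateau over the spawning days.
#' @param FP_effects 3 proximity effects (categories 0/1/2) on the log-rate
#'   scale; default increases with proximity.
#' @param sigma_h Per-station standard deviation(s) of the hour-level random
#'   effects; recycled to `n_stations`.
#' @param corr_decay_m E-folding distance (metres) of the exponential
#'   inter-station correlation kernel `R[j,k] = exp(-d_jk / corr_decay_m)`.
#' @param R Optional user-supplied station correlation matrix overriding the
#'   exponential kernel (projected to the nearest positive semidefinite
#'   correlation matrix if needed).
#' @param interference_frac Expected fraction of minutes carrying vessel
#'   interference (default 0.044, the array-wide share observed in field
#'   data of this kind).
#' @param classifier_tpr Probability that a true 2-s-bin call is detected by
#'   the simulated classifier.
#' @param classifier_fp_per_min Expected number of false-alarm detections per
#'   observed minute.
#' @param traj_sd_m Hourly standard deviation (metres) of the fish-mass
#'   random walk along the array.
#' @param traj_shift A list `list(at_hour =, offset_m =)` describing an
#'   optional persistent along-array shift of the fish mass, or `NULL`.
#' @param seed Root RNG seed; every generator stage derives an independent
#'   substream from it.
#'
#' @return An object of class `aas_config` (a named list).
#' @examples
#' cfg <- sim_config(n_stations = 3, n_hours = 24)
#' cfg$spacing_m
#' @export
sim_config <- function(n_stations = 6,
                       spacing_m = 150,
                       origin_lat = 19.70,
                       origin_lon = -80.10,
                       bearing_deg = 20,
                       start_time = "2020-02-08T10:00:00",
                       n_hours = 158,
                       first_spawn_hour = 86,
                       T_effects = default_T_effects(),
                       D_effects = default_D_effects(),
                       FP_effects = c(0, 0.6, 1.2),
                       sigma_h = 0.5,
                       corr_decay_m = 400,
                       R = NULL,
                       interference_frac = 0.044,
                       classifier_tpr = 0.7,
                       classifier_fp_per_min = 0.02,
                       traj_sd_m = 40,
                       traj_shift = NULL,
                       seed = 1L) {
  assert_scalar_number(n_stations, "n_stations", min = 1)
  assert_scalar_number(spacing_m, "spacing_m")
  if (spacing_m <= 0) abort("`spacing_m` must be positive")
  assert_scalar_number(origin_lat, "origin_lat", min = -90, max = 90)
  assert_scalar_number(origin_lon, "origin_lon", min = -180, max = 180)
  assert_scalar_number(n_hours, "n_hours", min = 1)
  assert_scalar_number(first_spawn_hour, "first_spawn_hour", min = 0)
  assert_scalar_number(interference_frac, "interference_frac", min = 0)
  if (interference_frac >= 1) abort("`interference_frac` must be < 1")
  assert_scalar_number(classifier_tpr, "classifier_tpr", min = 0, max = 1)
  assert_scalar_number(classifier_fp_per_min, "classifier_fp_per_min", min = 0)
  if (length(T_effects) != 24) abort("`T_effects` must have length 24")
  if (length(D_effects) != 7) abort("`D_effects` must have length 7")
  if (length(FP_effects) != 3) abort("`FP_effects` must have length 3")
  if (any(sigma_h < 0)) abort("`sigma_h` must be nonnegative")

  cfg <- list(
    n_stations = as.integer(n_stations),
    spacing_m = spacing_m,
    origin_lat = origin_lat,
    origin_lon = origin_lon,
    bearing_deg = bearing_deg,
    start_time = format_iso(parse_iso(start_time)),
    n_hours = as.integer(n_hours),
    first_spawn_hour = as.integer(first_spawn_hour),
    T_effects = as.numeric(T_effects),
    D_effects = as.numeric(D_effects),
    FP_effects = as.numeric(FP_effects),
    sigma_h = rep_len(as.numeric(sigma_h), as.integer(n_stations)),
    corr_decay_m = corr_decay_m,
    R = R,
    interference_frac = interference_frac,
    classifier_tpr = classifier_tpr,
    classifier_fp_per_min = classifier_fp_per_min,
    traj_sd_m = traj_sd_m,
    traj_shift = traj_shift,
    seed = as.integer(seed)
  )
  structure(cfg, class = "aas_config")
}

# Crepuscular hour-of-day template (log-rate by hour 0-23): dawn peak at
# 06:00-08:00, a higher dusk peak at 18:00-20:00, troughs in the middle of
# the night (02:00) and around midday (13:00).
default_T_effects <- function() {
  c(0.7, 0.5, 0.4, 0.5, 0.7, 1.0, 1.8, 2.1, 1.8, 1.2, 0.9, 0.8,
    0.7, 0.6, 0.7, 0.9, 1.0, 1.4, 2.2, 2.5, 2.2, 1.4, 1.0, 0.8)
}

# DAFS template: lowest on the first observed day (-4), rising to a high
# plateau on the spawning days (0..+2).
default_D_effects <- function() {
  c(-0.8, -0.5, -0.2, 0.1, 0.5, 0.6, 0.6)
}

#' @export
print.aas_config <- function(x, ...) {
  cat("<aas_config>\n")
  cat(sprintf("  stations: %d @ %.0f m spacing, bearing %.0f deg\n",
              x$n_stations, x$spacing_m, x$bearing_deg))
  cat(sprintf("  window:   %s + %d h (first spawn at hour %d)\n",
              x$start_time, x$n_hours, x$first_spawn_hour))
  cat(sprintf("  sigma_h:  %s; corr decay %.0f m\n",
              paste(format(x$sigma_h), collapse = ", "), x$corr_decay_m))
  cat(sprintf("  interference %.3f; classifier tpr %.2f, fp/min %.3f; seed %d\n",
              x$interference_frac, x$classifier_tpr, x$classifier_fp_per_min,
              x$seed))
  invisible(x)
}

#' Read or write a simulation configuration as YAML
#'
#' The configuration round-trips through a plain YAML file so that runs can be
#' reproduced from a single text artefact.
#'
#' @param path File path.
#' @return `read_sim_config()` returns an `aas_config`;
#'   `write_sim_config()` returns `path` invisibly.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$R <- if (!is.null(raw$R)) matrix(unlist(raw$R), nrow = length(raw$R))
  do.call(sim_config, raw)
}

#' @rdname read_sim_config
#' @param config An `aas_config`.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "aas_config"))
  out <- unclass(config)
  if (!is.null(out$R)) out$R <- apply(out$R, 1, as.numeric, simplify = FALSE)
  yaml::write_yaml(out, path)
  invisible(path)
}
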