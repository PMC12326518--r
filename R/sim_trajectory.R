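#' Simulate the fish-mass trajectory and per-station proximity categories
#'
#' The bulk of the aggregating fish is represented by a single latent
#' along-array position following a reflected Gaussian random walk (hourly
#' steps of SD `traj_sd_m`, reflected at the array ends padded by 100 m).
#' An optional persistent shift episode (`config$traj_shift`) displaces the
#' mass by a fixed along-array offset from a given hour onward, emulating an
#' aggregation relocating several hundred metres along the shelf. Each hour
#' the distance from the mass to every station yields the proximity category:
#' 2 ("present") within 20 m, 1 ("nearby") within 100 m, 0 otherwise.
#'
#' @param config An [sim_config()] object.
#' @param geometry Array geometry from [make_geometry()].
#' @param seed Optional seed override (defaults to the trajectory substream
#'   of `config$seed`).
#' @return A list with `positions` (tibble: `hour_index`, `hour_start`,
#'   `along_m`) and `proximity` (tibble: `station_id`, `hour_index`,
#'   `hour_start`, `distance_m`, `FP_index`).
#' @export
simulate_fsa_trajectory <- function(config, geometry, seed = NULL) {
  stopifnot(inherits(config, "aas_config"))
  if (nrow(geometry) == 0) abort("`geometry` must be nonempty")
  seed <- seed %||% substream_seeds(config$seed, "trajectory")[["trajectory"]]
  H <- config$n_hours
  lo <- min(geometry$along_m) - 100
  hi <- max(geometry$along_m) + 100
  pos <- with_seed(seed, {
    x <- numeric(H)
    x[1] <- mean(range(geometry$along_m))
    steps <- rnorm(H, 0, config$traj_sd_m)
    for (i in seq_len(H - 1)) x[i + 1] <- reflect(x[i] + steps[i], lo, hi)
    x
  })
  if (!is.null(config$traj_shift)) {
    sh <- config$traj_shift
    idx <- seq_len(H) > sh$at_hour
    pos[idx] <- reflect(pos[idx] + sh$offset_m, lo, hi)
  }
  hours <- parse_iso(config$start_time) + 3600 * (seq_len(H) - 1)
  positions <- tibble(hour_index = seq_len(H) - 1L, hour_start = hours,
                      along_m = pos)
  proximity <- tidyr::crossing(
    geometry[, c("station_id", "along_m")],
    positions[, c("hour_index", "hour_start")]
  ) %>%
    left_join(positions[, c("hour_index", "along_m")],
              by = "hour_index", suffix = c("_station", "_mass")) %>%
    mutate(distance_m = abs(.data$along_m_station - .data$along_m_mass),
           FP_index = proximity_category(.data$distance_m)) %>%
    select("station_id", "hour_index", "hour_start", "distance_m", "FP_index") %>%
    arrange(.data$station_id, .data$hour_index)
  list(positions = positions, proximity = proximity)
}

#' Distance-to-category rule for fish proximity
#'
#' Category 2 ("present") within 20 m of the station, 1 ("nearby") within
#' 100 m, 0 ("not observed") beyond 100 m.
#'
#' @param distance_m Nonnegative distances in metres.
#' @return Integer categories 0/1/2.
#' @export
proximity_category <- function(distance_m) {
  if (any(distance_m < 0, na.rm = TRUE)) abort("distances must be nonnegative")
  ifelse(distance_m <= 20, 2L, ifelse(distance_m <= 100, 1L, 0L))
}

reflect <- function(x, lo, hi) {
  w <- 2 * (hi - lo)
  y <- (x - lo) %% w
  lo + pmin(y, w - y)
}
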