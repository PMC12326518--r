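#' Generate per-minute interference flags for the observation window
#'
#' Vessel-noise interference is modelled as an independent Bernoulli process
#' over minutes with success probability `config$interference_frac`, so the
#' flagged share of minutes matches the configured expected fraction.
#'
#' @param config An [sim_config()] object.
#' @param seed RNG seed for this stage.
#' @return A tibble of minute records: `station_id`, `minute_start`,
#'   `interference` (logical).
#' @export
simulate_interference <- function(config, seed = 1L) {
  stopifnot(inherits(config, "aas_config"))
  start <- parse_iso(config$start_time)
  minutes <- start + 60 * (seq_len(config$n_hours * 60) - 1)
  geometry <- make_geometry(config)
  grid <- tidyr::crossing(station_id = geometry$station_id,
                          minute_start = minutes)
  grid$interference <- with_seed(
    seed, runif(nrow(grid)) < config$interference_frac
  )
  grid
}

#' Scatter hourly counts into per-minute 2-s detection bins
#'
#' Places each hour's `V` detections uniformly at random into distinct 2-s
#' bins (30 per minute) of that hour's interference-free minutes, honouring
#' the classifier convention of at most one call per 2-s bin. Detections are
#' never placed in interference-flagged minutes.
#'
#' @param hourcells Tibble with `station_id`, `hour_start`, `V` (e.g. from
#'   [simulate_hour_counts()], with `hour_start` present).
#' @param config An [sim_config()] object.
#' @param seed RNG seed for this stage.
#' @param minutes Optional precomputed minute records (from
#'   [simulate_interference()]); generated from `config` when `NULL`.
#' @return A list with `minutes` (the minute records used) and `events`
#'   (tibble `station_id`, `minute_start`, `bin_index` 0-29, sorted).
#' @export
simulate_minute_stream <- function(hourcells, config, seed = 1L,
                                   minutes = NULL) {
  stopifnot(inherits(config, "aas_config"))
  if (any(hourcells$V < 0)) abort("hourly counts must be nonnegative")
  if (is.null(minutes)) minutes <- simulate_interference(config, seed = seed)
  minutes <- minutes %>% mutate(hour_start = hour_floor(.data$minute_start))
  obs <- minutes[!minutes$interference, ]
  ok_list <- split(obs$minute_start,
                   paste(obs$station_id, format_iso(obs$hour_start)))

  placements <- with_seed(seed + 1, {
    purrr::pmap(
      list(hourcells$station_id, hourcells$hour_start, hourcells$V),
      function(st, hr, v) {
        if (v == 0) return(NULL)
        ok <- ok_list[[paste(st, format_iso(hr))]]
        if (is.null(ok)) ok <- parse_iso(character())
        if (length(ok) * 30 < v) {
          abort(sprintf(
            "station %s hour %s: %d detections exceed %d available 2-s bins",
            st, format_iso(hr), v, length(ok) * 30))
        }
        slot <- sample.int(length(ok) * 30, v)
        tibble(station_id = st,
               minute_start = ok[(slot - 1) %/% 30 + 1],
               bin_index = as.integer((slot - 1) %% 30))
      })
  })
  events <- bind_rows(placements)
  if (nrow(events) == 0) {
    events <- tibble(station_id = character(),
                     minute_start = parse_iso(character()),
                     bin_index = integer())
  }
  events <- arrange(events, .data$station_id, .data$minute_start,
                    .data$bin_index)
  list(minutes = select(minutes, -"hour_start"), events = events)
}

#' Simulate an imperfect classifier over a true detection stream
#'
#' Each true 2-s-bin detection is recovered independently with probability
#' `classifier_tpr`; false alarms are added in bins that carry no true
#' detection, each empty bin of an interference-free minute firing with
#' probability `classifier_fp_per_min / 30` (so the expected number of false
#' alarms per observed minute is approximately `classifier_fp_per_min` when
#' detections are sparse).
#'
#' @param true_events Event tibble (`station_id`, `minute_start`,
#'   `bin_index`).
#' @param minutes Minute records with `interference` flags.
#' @param config An [sim_config()] object.
#' @param seed RNG seed for this stage.
#' @return A list with `truth` (the input stream) and `predicted` (the
#'   classifier's stream, same columns).
#' @export
simulate_classifier <- function(true_events, minutes, config, seed = 1L) {
  stopifnot(inherits(config, "aas_config"))
  kept <- with_seed(seed, {
    true_events[runif(nrow(true_events)) < config$classifier_tpr, ]
  })
  p_bin <- config$classifier_fp_per_min / 30
  fps <- with_seed(seed + 1, {
    obs <- minutes[!minutes$interference, ]
    nfp <- rbinom(nrow(obs), 30, p_bin)
    idx <- rep.int(seq_len(nrow(obs)), nfp)
    if (length(idx) == 0) NULL else {
      tibble(station_id = obs$station_id[idx],
             minute_start = obs$minute_start[idx],
             bin_index = as.integer(unlist(lapply(nfp[nfp > 0], function(k)
               sample.int(30, k) - 1L)))) %>%
        anti_join(true_events,
                  by = c("station_id", "minute_start", "bin_index")) %>%
        distinct()
    }
  })
  predicted <- bind_rows(kept, fps)
  if (nrow(predicted) == 0) {
    predicted <- tibble(station_id = character(),
                        minute_start = parse_iso(character()),
                        bin_index = integer())
  }
  predicted <- arrange(predicted, .data$station_id, .data$minute_start,
                       .data$bin_index)
  list(truth = true_events, predicted = predicted)
}

#' Generate a complete synthetic hydrophone-array dataset
#'
#' Runs every generator stage in order under independent substreams of the
#' root seed: array geometry, fish-mass trajectory and proximity categories,
#' interference flags, effort-aware hourly counts from the hierarchical
#' Poisson process, per-minute detection placement, and the paired
#' true/predicted classifier streams.
#'
#' The effort `tau` entering the count process is the interference-free
#' fraction of each hour's minutes, so counts, streams and flags are mutually
#' consistent; hours with no interference-free minutes are dropped (none
#' occur at realistic interference fractions).
#'
#' @param config An [sim_config()] object.
#' @return A list: `config`, `geometry`, `params` (generating truth),
#'   `trajectory`, `proximity`, `minutes`, `hourcells` (with latent `h`,
#'   counts `V`, effort `tau`), `events`, `truth`, `predicted`.
#' @examples
#' sim <- simulate_dataset(sim_config(n_stations = 2, n_hours = 6, seed = 42))
#' head(sim$hourcells)
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "aas_config"))
  seeds <- substream_seeds(config$seed,
                           c("trajectory", "interference", "counts",
                             "placement", "classifier"))
  geometry <- make_geometry(config)
  traj <- simulate_fsa_trajectory(config, geometry, seed = seeds[["trajectory"]])
  params <- true_parameters(config, geometry)
  minutes <- simulate_interference(config, seed = seeds[["interference"]])
  tau_tbl <- minutes %>%
    mutate(hour_start = hour_floor(.data$minute_start)) %>%
    group_by(.data$station_id, .data$hour_start) %>%
    summarise(tau = mean(!.data$interference), .groups = "drop")
  design <- make_design(config, proximity = traj$proximity) %>%
    select(-"tau") %>%
    left_join(tau_tbl, by = c("station_id", "hour_start")) %>%
    filter(.data$tau > 0)
  hourcells <- simulate_hour_counts(params, design, seed = seeds[["counts"]])
  stream <- simulate_minute_stream(hourcells, config,
                                   seed = seeds[["placement"]],
                                   minutes = minutes)
  cls <- simulate_classifier(stream$events, minutes, config,
                             seed = seeds[["classifier"]])
  list(config = config, geometry = geometry, params = params,
       trajectory = traj$positions, proximity = traj$proximity,
       minutes = stream$minutes, hourcells = hourcells,
       events = stream$events, truth = cls$truth, predicted = cls$predicted)
}
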