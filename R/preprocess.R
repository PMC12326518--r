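#' Collapse within-minute call times to deduplicated 2-s bins
#'
#' Applies the classifier's segmentation convention: each minute is divided
#' into 30 fixed 2-s bins anchored at even seconds, at most one call is
#' attributable per bin, and when several calls fall in the same bin the
#' earliest is retained. Out-of-range call times are dropped with a warning.
#'
#' @param call_times Numeric seconds within the minute, each in `[0, 60)`.
#' @param station Station id for the emitted events.
#' @param minute Minute start (POSIXct or ISO-8601 string).
#' @return An event tibble (`station_id`, `minute_start`, `bin_index`,
#'   `call_time`) sorted by bin, one row per occupied 2-s bin.
#' @examples
#' bin_events(c(33.1, 33.8, 10), "LS1", "2020-02-08T10:00:00")
#' @export
bin_events <- function(call_times, station, minute) {
  minute <- parse_iso(minute)
  bad <- !is.finite(call_times) | call_times < 0 | call_times >= 60
  if (any(bad)) {
    warn(sprintf("dropping %d call time(s) outside [0, 60)", sum(bad)))
    call_times <- call_times[!bad]
  }
  if (length(call_times) == 0) {
    return(tibble(station_id = character(), minute_start = parse_iso(character()),
                  bin_index = integer(), call_time = numeric()))
  }
  tibble(bin_index = as.integer(floor(call_times / 2)),
         call_time = call_times) %>%
    group_by(.data$bin_index) %>%
    summarise(call_time = min(.data$call_time), .groups = "drop") %>%
    mutate(station_id = station, minute_start = minute) %>%
    select("station_id", "minute_start", "bin_index", "call_time") %>%
    arrange(.data$bin_index)
}

#' Select the 1-in-`period` annotation subsample of a minute record
#'
#' Deterministically marks every `period`-th minute, counting from the first
#' minute of each station's record, as sampled for annotation.
#'
#' @param minutes Minute records (`station_id`, `minute_start`, ...).
#' @param period Subsampling period (default 5: one annotated minute per
#'   five recorded).
#' @return The input with a logical `sampled` column added.
#' @export
subsample_minutes <- function(minutes, period = 5) {
  if (period < 1) abort("`period` must be >= 1")
  minutes %>%
    group_by(.data$station_id) %>%
    arrange(.data$minute_start, .by_group = TRUE) %>%
    mutate(sampled = (row_number() - 1L) %% period == 0L) %>%
    ungroup()
}

#' Expand flagged interference minutes into exclusion windows
#'
#' Because only the annotation subsample is inspected, an interference flag
#' is assumed to extend 2 minutes before and after the flagged minute; the
#' exclusion set is the union of the closed windows `[m - w, m + w]` over all
#' flagged sampled minutes, clipped to each station's record. Two flags five
#' minutes apart (e.g. 10:00 and 10:05) therefore yield one contiguous
#' 10-minute exclusion 09:58-10:07.
#'
#' @param minutes Minute records with `sampled` and `interference` columns.
#' @param window_min Half-width of the exclusion window in minutes
#'   (default 2).
#' @return The input with logical `excluded` and `observed` columns added
#'   (`observed = !excluded`).
#' @export
expand_interference <- function(minutes, window_min = 2) {
  if (!all(c("sampled", "interference") %in% names(minutes))) {
    abort("`minutes` needs `sampled` and `interference` columns; run subsample_minutes() first")
  }
  flagged <- minutes %>% filter(.data$sampled, .data$interference)
  windows <- tidyr::crossing(flagged[, c("station_id", "minute_start")],
                             offset = (-window_min):window_min) %>%
    mutate(minute_start = .data$minute_start + 60 * .data$offset) %>%
    distinct(.data$station_id, .data$minute_start)
  minutes %>%
    mutate(excluded = vctrs_in(minutes, windows),
           observed = !.data$excluded)
}

vctrs_in <- function(x, table) {
  paste(x$station_id, format_iso(x$minute_start)) %in%
    paste(table$station_id, format_iso(table$minute_start))
}

#' Compute per-hour annotation effort
#'
#' Effort is the fraction of the hour's minutes retained for analysis,
#' `tau = observed minutes / 60`, with a fixed denominator of 60 even for
#' partially recorded edge hours (their missing minutes simply count as
#' unobserved). Hours with zero observed minutes are dropped rather than
#' emitted with `tau = 0`, since a zero exposure carries no information for
#' the count model.
#'
#' @param minutes Minute records with an `observed` column (from
#'   [expand_interference()]).
#' @return A tibble `station_id`, `hour_start`, `minutes_observed`, `tau`
#'   with `tau` in (0, 1].
#' @export
compute_effort <- function(minutes) {
  if (!"observed" %in% names(minutes)) {
    abort("`minutes` needs an `observed` column; run expand_interference() first")
  }
  out <- minutes %>%
    mutate(hour_start = hour_floor(.data$minute_start)) %>%
    group_by(.data$station_id, .data$hour_start) %>%
    summarise(minutes_observed = sum(.data$observed), .groups = "drop") %>%
    mutate(tau = .data$minutes_observed / 60)
  dropped <- sum(out$tau == 0)
  if (dropped > 0) {
    rlang::inform(sprintf("dropping %d station-hour(s) with no observable minutes", dropped))
  }
  filter(out, .data$tau > 0)
}

#' Aggregate deduplicated detections into model-ready hour cells
#'
#' Sums detections per station and hour over observed minutes, attaches the
#' effort `tau` and the covariate indices, and computes the effort-normalised
#' rate `V / tau`. Events lying in non-observed minutes are a pipeline
#' ordering violation (interference exclusion must happen first) and raise an
#' error; use [filter_events_observed()] upstream.
#'
#' @param events Event tibble (`station_id`, `minute_start`, `bin_index`).
#' @param minutes Minute records with `observed` (from
#'   [expand_interference()]).
#' @param covariates Optional tibble keyed by `station_id`, `hour_start`
#'   carrying `T_index`, `D_index`, `FP_index` (e.g. a [make_design()]
#'   grid); when `NULL`, `T_index` is derived from the hour and `D_index`,
#'   `FP_index` are left out.
#' @return An hour-cell tibble: `station_id`, `hour_start`, `V`, `tau`,
#'   `rate`, plus covariate index columns, one row per station-hour with
#'   `tau > 0`.
#' @export
aggregate_hourly <- function(events, minutes, covariates = NULL) {
  effort <- compute_effort(minutes)
  if (nrow(events) > 0) {
    obs <- minutes %>% filter(.data$observed)
    if (!all(vctrs_in(events, obs))) {
      abort("events found in non-observed minutes; filter_events_observed() must run first")
    }
    if (anyDuplicated(events[, c("station_id", "minute_start", "bin_index")])) {
      abort("duplicate events in the same 2-s bin; run bin_events() first")
    }
  }
  counts <- events %>%
    mutate(hour_start = hour_floor(.data$minute_start)) %>%
    count(.data$station_id, .data$hour_start, name = "V")
  out <- effort %>%
    left_join(counts, by = c("station_id", "hour_start")) %>%
    mutate(V = as.integer(dplyr::coalesce(.data$V, 0L)),
           rate = .data$V / .data$tau,
           T_index = as.integer(format(.data$hour_start, "%H")))
  if (!is.null(covariates)) {
    keep <- intersect(c("station_id", "hour_start", "D_index", "FP_index"),
                      names(covariates))
    out <- left_join(out, covariates[, keep], by = c("station_id", "hour_start"))
  }
  arrange(out, .data$station_id, .data$hour_start)
}

#' Drop events falling in non-observed minutes
#'
#' @param events Event tibble.
#' @param minutes Minute records with `observed`.
#' @return The events restricted to observed minutes.
#' @export
filter_events_observed <- function(events, minutes) {
  obs <- minutes %>% filter(.data$observed)
  events[vctrs_in(events, obs), ]
}

#' Categorise a MaxN abundance count
#'
#' Standard video-census abundance classes: absent (0), individual (1), few
#' (2-10; class 2), many (11-100; class 3), abundant (>100; class 4).
#'
#' @param maxn Nonnegative integer MaxN counts.
#' @return Integer categories 0-4.
#' @examples
#' categorize_maxn(c(0, 1, 7, 45, 150))
#' @export
categorize_maxn <- function(maxn) {
  if (any(maxn < 0 | !is.finite(maxn))) abort("`maxn` must be nonnegative")
  cut(maxn, breaks = c(-0.5, 0.5, 1.5, 10.5, 100.5, Inf),
      labels = FALSE) - 1L
}

#' Combine sourced distance observations into a composite proximity category
#'
#' Multiple observation sources (cameras, diver notes, video transects) each
#' claim a distance class for the fish mass relative to a station-hour. The
#' composite category takes the most informative claim: 2 ("present") if any
#' source puts the bulk within 20 m, else 1 ("nearby") if any source puts it
#' within 100 m, else 0 ("not observed").
#'
#' @param observations A tibble with columns `station_id`, `hour_start` and
#'   `distance_class` (one of `"within20"`, `"within100"`, `"beyond"`).
#' @return A tibble `station_id`, `hour_start`, `FP_index` (0/1/2).
#' @export
composite_proximity <- function(observations) {
  lv <- c(beyond = 0L, within100 = 1L, within20 = 2L)
  if (!all(observations$distance_class %in% names(lv))) {
    abort("`distance_class` must be one of 'within20', 'within100', 'beyond'")
  }
  observations %>%
    mutate(score = lv[.data$distance_class]) %>%
    group_by(.data$station_id, .data$hour_start) %>%
    summarise(FP_index = max(.data$score), .groups = "drop")
}
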