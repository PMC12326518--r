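#' Encode hour cells into dense model arrays
#'
#' Maps an hour-cell table to the index arrays consumed by the call-rate
#' model: counts `V`, exposure offsets `log_tau`, the three covariate index
#' vectors, and station/hour integer maps. Optionally restricts to hours
#' observed by every station (the complete-case window used when a station
#' fails partway through a deployment). Ordering is deterministic: station,
#' then hour.
#'
#' @param hourcells Tibble with `station_id`, `hour_start`, `V`, `tau`,
#'   `T_index`, `D_index`, `FP_index`.
#' @param complete_hours If `TRUE` (default), keep only hours present for
#'   all stations.
#' @return An object of class `aas_design`: a list with vectors `V`,
#'   `log_tau`, `T_index`, `D_index`, `FP_index`, `station`, `hour`
#'   (1-based), `stations`, `hours`, and scalars `J`, `H`, `n`.
#' @export
encode_design <- function(hourcells, complete_hours = TRUE) {
  need <- c("station_id", "hour_start", "V", "tau", "T_index", "D_index",
            "FP_index")
  if (!all(need %in% names(hourcells))) {
    abort(paste("`hourcells` needs columns:", paste(need, collapse = ", ")))
  }
  if (nrow(hourcells) == 0) abort("`hourcells` is empty")
  if (any(hourcells$tau <= 0 | hourcells$tau > 1)) {
    abort("`tau` must lie in (0, 1]")
  }
  if (anyDuplicated(hourcells[, c("station_id", "hour_start")])) {
    abort("duplicate (station, hour) cells")
  }
  check_indices(hourcells)
  hc <- hourcells
  if (complete_hours) {
    J_all <- length(unique(hc$station_id))
    full <- hc %>% count(.data$hour_start) %>% filter(.data$n == J_all)
    hc <- semi_join(hc, full, by = "hour_start")
    if (nrow(hc) == 0) abort("no hours observed by all stations")
  }
  hc <- arrange(hc, .data$station_id, .data$hour_start)
  stations <- sort(unique(hc$station_id))
  hours <- sort(unique(hc$hour_start))
  structure(list(
    V = as.integer(hc$V),
    log_tau = log(hc$tau),
    T_index = as.integer(hc$T_index),
    D_index = as.integer(hc$D_index),
    FP_index = as.integer(hc$FP_index),
    station = match(hc$station_id, stations),
    hour = match(hc$hour_start, hours),
    stations = stations,
    hours = hours,
    J = length(stations),
    H = length(hours),
    n = nrow(hc)
  ), class = "aas_design")
}

#' @export
print.aas_design <- function(x, ...) {
  cat(sprintf("<aas_design> %d cells: %d stations x %d hours\n",
              x$n, x$J, x$H))
  invisible(x)
}
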