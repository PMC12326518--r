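#' Lay out the hydrophone array on the sphere
#'
#' Places `n_stations` points `spacing_m` metres apart along a great-circle
#' line from the origin, alternating the two instrument models (LS and ST)
#' along the array as in typical mixed deployments.
#'
#' @param config An [sim_config()] object.
#' @return A tibble with columns `station_id`, `instrument` (`"LS"`/`"ST"`),
#'   `lat`, `lon`, and `along_m` (distance from the first station along the
#'   array line).
#' @examples
#' make_geometry(sim_config(n_stations = 3))
#' @export
make_geometry <- function(config) {
  stopifnot(inherits(config, "aas_config"))
  n <- config$n_stations
  along <- (seq_len(n) - 1) * config$spacing_m
  pts <- geosphere::destPoint(
    p = c(config$origin_lon, config$origin_lat),
    b = config$bearing_deg, d = along, r = earth_radius_m()
  )
  inst <- rep(c("LS", "ST"), length.out = n)
  tibble(
    station_id = sprintf("%s%d", inst, seq_len(n)),
    instrument = inst,
    lat = pts[, "lat"],
    lon = pts[, "lon"],
    along_m = along
  )
}

#' Spherical Earth radius used throughout the package
#'
#' The WGS84 equatorial radius (6,378,137 m), the default of the common
#' geographic distance tools; all great-circle computations in the package
#' use it so distances are mutually consistent.
#' @return Radius in metres.
#' @export
earth_radius_m <- function() 6378137

#' Pairwise great-circle distance matrix for an array geometry
#'
#' Haversine distances on a sphere of radius [earth_radius_m()].
#'
#' @param geometry A tibble with `station_id`, `lat`, `lon` columns (from
#'   [make_geometry()] or user data).
#' @return A symmetric matrix of distances in metres with zero diagonal,
#'   dimnames set to the station ids.
#' @export
haversine_matrix <- function(geometry) {
  check_geometry(geometry)
  m <- geosphere::distm(
    cbind(geometry$lon, geometry$lat),
    fun = function(p1, p2) geosphere::distHaversine(p1, p2, r = earth_radius_m())
  )
  dimnames(m) <- list(geometry$station_id, geometry$station_id)
  m
}

check_geometry <- function(geometry) {
  if (!all(c("station_id", "lat", "lon") %in% names(geometry))) {
    abort("`geometry` needs columns station_id, lat, lon")
  }
  if (anyDuplicated(geometry$station_id)) abort("station ids must be unique")
  if (any(abs(geometry$lat) > 90) || any(abs(geometry$lon) > 180) ||
      any(!is.finite(geometry$lat)) || any(!is.finite(geometry$lon))) {
    abort("invalid station coordinates")
  }
  invisible(geometry)
}
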