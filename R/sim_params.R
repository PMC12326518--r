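#' Assemble the generating parameter set for the hourly count process
#'
#' Builds the "truth" used by [simulate_hour_counts()]: the 24 hour-of-day
#' effects, 7 day-after-first-spawn effects, 3 proximity effects, per-station
#' random-effect SDs, and the station correlation matrix. By default the
#' correlation matrix follows an exponential distance kernel
#' `R[j,k] = exp(-d_jk / corr_decay_m)`, which is always a valid correlation
#' matrix and reproduces the qualitative decay of inter-station correlation
#' with distance; a user matrix in `config$R` overrides it (projected to the
#' nearest positive semidefinite correlation matrix if necessary).
#'
#' @param config An [sim_config()] object.
#' @param geometry Array geometry (from [make_geometry()]); required unless
#'   `config$R` is supplied.
#' @return An object of class `aas_parameters`: a list with elements `T`
#'   (24), `D` (7), `FP` (3), `sigma_h` (J), `R` (J x J) and `station_id`.
#' @export
true_parameters <- function(config, geometry = NULL) {
  stopifnot(inherits(config, "aas_config"))
  J <- config$n_stations
  if (!is.null(config$R)) {
    R <- as_correlation(config$R)
    ids <- colnames(R) %||% sprintf("S%d", seq_len(J))
  } else {
    if (is.null(geometry)) geometry <- make_geometry(config)
    d <- haversine_matrix(geometry)
    R <- exp(-d / config$corr_decay_m)
    ids <- geometry$station_id
  }
  dimnames(R) <- list(ids, ids)
  if (nrow(R) != J) abort("correlation matrix dimension != n_stations")
  structure(
    list(T = config$T_effects, D = config$D_effects, FP = config$FP_effects,
         sigma_h = config$sigma_h, R = R, station_id = ids),
    class = "aas_parameters"
  )
}

# Validate/repair a correlation matrix: symmetrise, unit diagonal, clip tiny
# negative eigenvalues, project to nearest PSD correlation matrix if needed.
as_correlation <- function(R, tol = 1e-10) {
  R <- as.matrix(R)
  if (nrow(R) != ncol(R)) abort("correlation matrix must be square")
  R <- (R + t(R)) / 2
  diag(R) <- 1
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < -tol) {
    # Higham-style projection: clip eigenvalues, rescale to unit diagonal
    vals <- pmax(ev$values, tol)
    R <- ev$vectors %*% diag(vals) %*% t(ev$vectors)
    s <- 1 / sqrt(diag(R))
    R <- R * tcrossprod(s)
    diag(R) <- 1
    R <- (R + t(R)) / 2
  }
  if (any(abs(R) > 1 + 1e-8)) abort("correlation entries outside [-1, 1]")
  pmin(pmax(R, -1), 1)
}

check_parameters <- function(params, J = NULL) {
  stopifnot(inherits(params, "aas_parameters") || is.list(params))
  if (length(params$T) != 24) abort("`T` must have 24 entries")
  if (length(params$D) != 7) abort("`D` must have 7 entries")
  if (length(params$FP) != 3) abort("`FP` must have 3 entries")
  if (any(params$sigma_h < 0)) abort("`sigma_h` must be nonnegative")
  R <- params$R
  if (!isTRUE(all.equal(R, t(R), tolerance = 1e-8))) abort("R not symmetric")
  if (any(abs(diag(R) - 1) > 1e-8)) abort("R diagonal must be 1")
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-10) {
    abort("R not positive semidefinite")
  }
  if (!is.null(J) && length(params$sigma_h) != J) {
    abort("`sigma_h` length must equal station count")
  }
  invisible(params)
}
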