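# Correlation-matrix machinery: canonical partial correlations (CPCs), the
# unconstrained <-> Cholesky transform used by the sampler, and the exact LKJ
# log density via the C-vine factorization (partial correlations at vine tree
# level l are independent symmetric-Beta on (-1,1) with shape
# alpha_l = eta + (d - 1 - l) / 2).

# Lower Cholesky factor of a correlation matrix from CPCs z (column-major
# lower triangle: z[i, j] for j < i, supplied as a vector).
chol_from_cpc <- function(z, d) {
  if (d == 1) return(matrix(1, 1, 1))
  L <- diag(d)
  k <- 0
  for (j in seq_len(d - 1)) {
    for (i in (j + 1):d) {
      k <- k + 1
      rem <- 1 - if (j > 1) sum(L[i, 1:(j - 1)]^2) else 0
      L[i, j] <- z[k] * sqrt(max(rem, 0))
    }
  }
  for (i in 2:d) {
    L[i, i] <- sqrt(max(1 - sum(L[i, 1:(i - 1)]^2), 0))
  }
  L
}

# Inverse: CPCs from a correlation matrix via its Cholesky factor.
cpc_from_R <- function(R) {
  d <- nrow(R)
  L <- t(chol(R))
  z <- numeric(d * (d - 1) / 2)
  k <- 0
  for (j in seq_len(d - 1)) {
    for (i in (j + 1):d) {
      k <- k + 1
      rem <- 1 - if (j > 1) sum(L[i, 1:(j - 1)]^2) else 0
      z[k] <- L[i, j] / sqrt(max(rem, .Machine$double.eps))
    }
  }
  z
}

# Vine tree level (conditioning-set size + 1) of each CPC, matching the
# ordering in chol_from_cpc: level equals the column index j.
cpc_levels <- function(d) {
  unlist(lapply(seq_len(d - 1), function(j) rep(j, d - j)))
}

# log density of one CPC under LKJ(eta): symmetric Beta on (-1, 1) with
# alpha = eta + (d - 1 - level) / 2.
cpc_log_density <- function(z, level, d, eta) {
  alpha <- eta + (d - 1 - level) / 2
  (alpha - 1) * log1p(-z^2) - (2 * alpha - 1) * log(2) - lbeta(alpha, alpha)
}

#' Exact LKJ log density of a correlation matrix
#'
#' Evaluates the LKJ(eta) density, normalizing constant included, through
#' the C-vine factorization: the canonical partial correlations of `R` are
#' independent symmetric-Beta variates, and the Jacobian of the partial
#' correlation to correlation map is a product of powers of `1 - z^2`. At
#' `eta = 1` the density is constant over the space of valid correlation
#' matrices (e.g. `-log(2)` for 2 x 2 matrices).
#'
#' @param R A correlation matrix.
#' @param eta LKJ shape (default 1 = uniform over correlation matrices).
#' @return The log density (a scalar).
#' @export
lkj_log_density <- function(R, eta = 1) {
  d <- nrow(R)
  if (d < 2) return(0)
  z <- cpc_from_R(R)
  lev <- cpc_levels(d)
  dens <- sum(cpc_log_density(z, lev, d, eta))
  # Jacobian of z -> R: prod over CPCs of (1 - z^2)^((d - 1 - level) / 2)
  log_jac <- sum((d - 1 - lev) / 2 * log1p(-z^2))
  dens - log_jac
}

# --- unconstrained parameterization used by the sampler ---------------------

# y (unconstrained) -> z = tanh(y) -> L; returns list with L, z and the log
# of prior density + Jacobian terms for the MCMC target:
#   log LKJ-vine prior on z  +  log |dz/dy| = sum log(1 - z^2)
corr_transform <- function(y, d, eta = 1) {
  z <- tanh(y)
  L <- chol_from_cpc(z, d)
  lev <- cpc_levels(d)
  lp <- sum(cpc_log_density(z, lev, d, eta)) + sum(log1p(-z^2))
  list(L = L, z = z, lp = lp)
}

corr_untransform <- function(R) {
  atanh(pmin(pmax(cpc_from_R(R), -1 + 1e-12), 1 - 1e-12))
}
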