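#' Log joint density of the hierarchical call-rate model
#'
#' Evaluates the full log joint (likelihood plus priors, all normalizing
#' constants included) of the hierarchical Poisson model at a given
#' parameter set:
#' \deqn{V_{j,i} \sim \mathrm{Poisson}(\mu_{j,i}), \quad
#'       \log \mu_{j,i} = \log \tau_{j,i} + T_i + D_i + FP_{j,i} + h_{j,i}}
#' with the hour-level station random-effect vectors
#' \eqn{h_{\cdot,i} \sim \mathrm{MVN}(0, \,\mathrm{diag}(\sigma_h)\, R\,
#' \mathrm{diag}(\sigma_h))}, standard-normal priors on every `T`, `D` and
#' `FP` entry, independent Exponential(1) priors on each station SD
#' \eqn{\sigma_h}, and an LKJ(1) prior on the correlation matrix `R`.
#'
#' @param params A list with `T` (24), `D` (7), `FP` (3), `sigma_h` (J),
#'   `R` (J x J correlation matrix) and `h` (H x J matrix of hour-level
#'   random effects, columns ordered as `design$stations`).
#' @param design An `aas_design` from [encode_design()].
#' @return The scalar log joint density.
#' @export
log_joint <- function(params, design) {
  stopifnot(inherits(design, "aas_design"))
  check_parameters(params, J = design$J)
  if (any(params$sigma_h <= 0)) abort("`sigma_h` must be positive")
  h <- as.matrix(params$h)
  if (nrow(h) != design$H || ncol(h) != design$J) {
    abort(sprintf("`h` must be %d x %d", design$H, design$J))
  }
  Sigma <- diag(params$sigma_h, design$J) %*% params$R %*%
    diag(params$sigma_h, design$J)
  ch <- tryCatch(chol(Sigma), error = function(e) {
    abort("covariance diag(sigma_h) R diag(sigma_h) is not positive definite")
  })

  eta <- design$log_tau + params$T[design$T_index + 1] +
    params$D[design$D_index + 1] + params$FP[design$FP_index + 1] +
    h[cbind(design$hour, design$station)]
  pois <- sum(design$V * eta - exp(eta) - lgamma(design$V + 1))

  logdet <- 2 * sum(log(diag(ch)))
  zq <- backsolve(ch, t(h), transpose = TRUE) # J x H, solves t(ch) %*% x = t(h)
  mvn <- -0.5 * design$H * (design$J * log(2 * pi) + logdet) -
    0.5 * sum(zq^2)

  priors <- sum(stats::dnorm(c(params$T, params$D, params$FP), log = TRUE)) +
    sum(stats::dexp(params$sigma_h, rate = 1, log = TRUE)) +
    lkj_log_density(params$R, eta = 1)

  pois + mvn + priors
}
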