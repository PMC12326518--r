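#' MCMC convergence diagnostics: split R-hat and effective sample size
#'
#' Computes the split Gelman-Rubin statistic (each chain halved, potential
#' scale reduction across the resulting sequences) and an
#' autocorrelation-based effective sample size (Geyer initial positive
#' sequence) for every selected parameter. The overall `pass` attribute is
#' `TRUE` when every R-hat is below 1.05.
#'
#' @param fit An `aas_fit`.
#' @param pars Regular expression selecting parameter columns (default: all
#'   except `lp__`).
#' @param rhat_limit Convergence threshold (default 1.05).
#' @return A tibble `term`, `rhat`, `ess` with attribute `pass`; R-hat is
#'   `NA` (with a warning) when the fit has a single chain.
#' @export
convergence <- function(fit, pars = NULL, rhat_limit = 1.05) {
  stopifnot(inherits(fit, "aas_fit"))
  pars <- pars %||% "^(?!lp__).*$"
  cols <- grep(pars, colnames(fit$draws), value = TRUE, perl = TRUE)
  single <- fit$chains < 2
  if (single) warn("R-hat requires at least 2 chains; returning NA")
  out <- purrr::map_dfr(cols, function(cn) {
    m <- matrix(fit$draws[, cn], ncol = fit$chains)
    tibble(term = cn,
           rhat = if (single) NA_real_ else split_rhat(m),
           ess = ess_mean(m))
  })
  attr(out, "pass") <- !single && all(out$rhat < rhat_limit, na.rm = TRUE)
  out
}

# split-half R-hat over an iterations x chains matrix
split_rhat <- function(draws) {
  n <- nrow(draws)
  half <- floor(n / 2)
  if (half < 2) return(NA_real_)
  sp <- cbind(draws[seq_len(half), , drop = FALSE],
              draws[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sp)
  means <- colMeans(sp)
  vars <- apply(sp, 2, var)
  W <- mean(vars)
  B <- half * var(means)
  if (W == 0) return(NA_real_)
  sqrt(((half - 1) / half * W + B / half) / W)
}

# effective sample size for the mean, combining chains (split in half),
# using the mean within-chain autocovariance and Geyer's initial positive
# sequence truncation
ess_mean <- function(draws) {
  n <- nrow(draws)
  half <- floor(n / 2)
  if (half < 4) return(NA_real_)
  sp <- cbind(draws[seq_len(half), , drop = FALSE],
              draws[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sp)
  vars <- apply(sp, 2, var)
  W <- mean(vars)
  if (W == 0) return(NA_real_)
  B <- half * var(colMeans(sp))
  var_plus <- (half - 1) / half * W + B / half
  acov <- apply(sp, 2, function(x) {
    a <- stats::acf(x, lag.max = half - 1, type = "covariance",
                    plot = FALSE, demean = TRUE)$acf[, 1, 1]
    a * (half - 1) / half
  })
  rho <- 1 - (W - rowMeans(acov)) / var_plus
  rho[1] <- 1
  # Geyer initial positive sequence: tau = -1 + 2 * sum of positive
  # consecutive pairs (rho_0 + rho_1), (rho_2 + rho_3), ...
  tau <- -1
  t <- 0
  while (t + 2 <= length(rho)) {
    pair <- rho[t + 1] + rho[t + 2]
    if (!is.finite(pair) || pair <= 0) break
    tau <- tau + 2 * pair
    t <- t + 2
  }
  ess <- m * half / max(tau, 1e-8)
  min(ess, m * half)
}
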