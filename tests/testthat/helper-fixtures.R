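# shared fixture builders -----------------------------------------------------

tiny_config <- function(...) {
  sim_config(n_stations = 2, n_hours = 6, interference_frac = 0.05,
             seed = 42, ...)
}

# a design grid with hand-picked covariate indices, bypassing the calendar
flat_design <- function(n_cells, stations = "S1", tau = 1,
                        T_index = 0L, D_index = 0L, FP_index = 0L) {
  tidyr::crossing(station_id = stations,
                  hour_index = seq_len(n_cells / length(stations)) - 1L) %>%
    dplyr::mutate(
      hour_start = as.POSIXct("2020-02-08 00:00:00", tz = "UTC") +
        3600 * hour_index,
      tau = tau, T_index = T_index, D_index = D_index, FP_index = FP_index)
}

flat_params <- function(J = 1, sigma_h = 0, R = diag(J), value = 0,
                        ids = sprintf("S%d", seq_len(J))) {
  dimnames(R) <- list(ids, ids)
  structure(list(T = rep(value, 24), D = rep(value, 7), FP = rep(value, 3),
                 sigma_h = rep(sigma_h, J), R = R, station_id = ids),
            class = "aas_parameters")
}

# independent brute-force log-joint oracle (naive loops; base R only)
oracle_log_joint <- function(params, design) {
  S <- diag(params$sigma_h) %*% params$R %*% diag(params$sigma_h)
  Sinv <- solve(S)
  ld <- as.numeric(determinant(S, logarithm = TRUE)$modulus)
  h <- as.matrix(params$h)
  lp <- 0
  for (k in seq_len(design$n)) {
    mu <- exp(design$log_tau[k]) *
      exp(params$T[design$T_index[k] + 1] + params$D[design$D_index[k] + 1] +
            params$FP[design$FP_index[k] + 1] +
            h[design$hour[k], design$station[k]])
    lp <- lp + dpois(design$V[k], mu, log = TRUE)
  }
  for (i in seq_len(design$H)) {
    lp <- lp - 0.5 * (design$J * log(2 * pi) + ld +
                        drop(t(h[i, ]) %*% Sinv %*% h[i, ]))
  }
  lp + sum(dnorm(c(params$T, params$D, params$FP), log = TRUE)) +
    sum(dexp(params$sigma_h, log = TRUE)) +
    oracle_lkj1_const(design$J)
}

# LKJ(1) log density constant = -log(volume of the correlation-matrix
# elliptope), via the integral identity
# int_{-1}^{1} (1 - z^2)^(a-1) dz = 2^(2a-1) Beta(a, a)
oracle_lkj1_const <- function(d) {
  if (d < 2) return(0)
  logvol <- 0
  for (j in seq_len(d - 1)) {
    a <- (d + 1 - j) / 2
    logvol <- logvol + (d - j) * ((2 * a - 1) * log(2) + lbeta(a, a))
  }
  -logvol
}

# random valid correlation matrix
random_corr <- function(d) {
  A <- matrix(rnorm(d * d), d)
  stats::cov2cor(crossprod(A) + diag(d) * 0.1)
}

# minimal fitted-model stand-in carrying only correlation draws, for spatial
# operations that need an aas_fit
fake_fit <- function(R_draws, stations) {
  J <- length(stations)
  pairs <- which(upper.tri(diag(J)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, "col"], pairs[, "row"]), , drop = FALSE]
  cols <- sprintf("R[%s,%s]", stations[pairs[, "row"]],
                  stations[pairs[, "col"]])
  draws <- t(vapply(R_draws, function(R) R[upper.tri(R)],
                    numeric(nrow(pairs))))
  colnames(draws) <- cols
  structure(list(draws = draws, chain = rep(1L, length(R_draws)),
                 iteration = seq_along(R_draws),
                 design = list(stations = stations, J = J),
                 chains = 1L),
            class = "aas_fit")
}
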