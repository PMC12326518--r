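# Hamiltonian Monte Carlo machinery for the hierarchical call-rate model.
#
# The unconstrained parameter vector is
#   theta = [T (24), D (7), FP (3), log sigma_h (J), y (J(J-1)/2), h (H*J)]
# with sigma_h = exp(ls) (Exponential(1) prior + log Jacobian) and the
# correlation matrix parameterized by canonical partial correlations
# z = tanh(y) (LKJ vine prior + tanh Jacobian). h is centered.
#
# Gradients for T, D, FP and h are analytic. The 15-odd covariance
# parameters (ls, y) enter the target only through the h-likelihood trace
# form and their priors, an O(J^3) subfunction; their gradient uses central
# finite differences on that subfunction, which is exact to ~1e-9 and costs
# a negligible share of a gradient evaluation.

target_layout <- function(design) {
  J <- design$J
  m <- J * (J - 1) / 2
  sizes <- c(T = 24, D = 7, FP = 3, ls = J, y = m, h = design$H * J)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1
  list(sizes = sizes, idx = purrr::map2(starts, ends, seq),
       dim = sum(sizes))
}

unpack_theta <- function(theta, design, layout) {
  list(
    T = theta[layout$idx$T],
    D = theta[layout$idx$D],
    FP = theta[layout$idx$FP],
    ls = theta[layout$idx$ls],
    y = theta[layout$idx$y],
    h = matrix(theta[layout$idx$h], design$H, design$J)
  )
}

# covariance-parameter subtarget: h-likelihood terms that depend on
# (ls, y) through Sigma, plus the sigma and correlation priors/Jacobians.
# S = crossprod(h) is fixed while differentiating.
cov_subtarget <- function(ls, y, S, H, J) {
  ct <- corr_transform(y, J)
  sigma <- exp(ls)
  Lsig <- sigma * ct$L # diag(sigma) %*% L
  dl <- diag(Lsig)
  if (any(dl <= 0) || any(!is.finite(dl))) return(-Inf)
  Linv <- forwardsolve(Lsig, diag(J))
  logdet <- 2 * sum(log(dl))
  tr <- sum((Linv %*% S) * Linv)
  -0.5 * H * logdet - 0.5 * tr - sum(sigma) + sum(ls) + ct$lp
}

make_target <- function(design) {
  layout <- target_layout(design)
  J <- design$J
  H <- design$H
  cell <- cbind(design$hour, design$station)
  Ti <- design$T_index + 1
  Di <- design$D_index + 1
  Fi <- design$FP_index + 1
  lgamV <- lgamma(design$V + 1)
  eps_fd <- 1e-5

  lp_grad <- function(theta) {
    if (any(!is.finite(theta))) return(list(lp = -Inf, grad = NULL))
    p <- unpack_theta(theta, design, layout)
    ct <- corr_transform(p$y, J)
    sigma <- exp(p$ls)
    if (any(!is.finite(sigma))) return(list(lp = -Inf, grad = NULL))
    Lsig <- sigma * ct$L
    dl <- diag(Lsig)
    if (any(!is.finite(dl)) || any(dl <= 1e-12)) {
      return(list(lp = -Inf, grad = NULL))
    }
    Linv <- forwardsolve(Lsig, diag(J))
    Sinv <- crossprod(Linv)

    eta <- design$log_tau + p$T[Ti] + p$D[Di] + p$FP[Fi] + p$h[cell]
    mu <- exp(eta)
    pois <- sum(design$V * eta - mu - lgamV)

    S <- crossprod(p$h)
    logdet <- 2 * sum(log(diag(Lsig)))
    mvn <- -0.5 * H * (J * log(2 * pi) + logdet) - 0.5 * sum(Sinv * S)

    lp <- pois + mvn +
      sum(stats::dnorm(c(p$T, p$D, p$FP), log = TRUE)) -
      sum(sigma) + sum(p$ls) + ct$lp

    if (!is.finite(lp)) return(list(lp = -Inf, grad = NULL))

    gc <- design$V - mu
    acc <- function(g, idx, k) {
      out <- numeric(k)
      s <- rowsum(g, idx)
      out[as.integer(rownames(s))] <- s
      out
    }
    gT <- acc(gc, Ti, 24) - p$T
    gD <- acc(gc, Di, 7) - p$D
    gF <- acc(gc, Fi, 3) - p$FP
    gh <- matrix(0, H, J)
    gh[cell] <- gc
    gh <- gh - p$h %*% Sinv

    ncov <- J + length(p$y)
    gcov <- numeric(ncov)
    base <- c(p$ls, p$y)
    for (k in seq_len(ncov)) {
      up <- base; up[k] <- up[k] + eps_fd
      dn <- base; dn[k] <- dn[k] - eps_fd
      gcov[k] <- (cov_subtarget(up[seq_len(J)], up[-seq_len(J)], S, H, J) -
                    cov_subtarget(dn[seq_len(J)], dn[-seq_len(J)], S, H, J)) /
        (2 * eps_fd)
    }

    list(lp = lp, grad = c(gT, gD, gF, gcov, as.numeric(gh)))
  }

  # Exact line-Gibbs update along the likelihood-flat additive directions
  # (T + c, D - c) and (T + c, FP - c): every cell carries exactly one T, one
  # D and one FP index, so the Poisson term is invariant and the conditional
  # of the shift c is Gaussian from the standard-normal priors. This removes
  # the slowly mixing level trade-off that index coding without a reference
  # level otherwise leaves to the trajectory sampler.
  recenter <- function(theta) {
    iT <- layout$idx$T
    for (other in list(layout$idx$D, layout$idx$FP)) {
      prec <- length(iT) + length(other)
      shift <- rnorm(1, (sum(theta[other]) - sum(theta[iT])) / prec,
                     1 / sqrt(prec))
      theta[iT] <- theta[iT] + shift
      theta[other] <- theta[other] - shift
    }
    theta
  }

  # Category-level recentering: for each hour-of-day category t the direction
  # (T_t + c, h[hours in t, ] - c) leaves every Poisson mean unchanged, and
  # the conditional of c is Gaussian from the T prior and the MVN prior of
  # h (likewise for D by study day, and for FP over its per-cell station
  # pattern). These exact Gibbs draws mix the level trade-off between the
  # category effects and the random effects.
  hour_T <- integer(H); hour_T[design$hour] <- design$T_index # per-hour index
  hour_D <- integer(H); hour_D[design$hour] <- design$D_index
  FP_mask <- lapply(0:2, function(f) {
    M <- matrix(0, H, J)
    sel <- design$FP_index == f
    M[cbind(design$hour[sel], design$station[sel])] <- 1
    M
  })
  cat_recenter <- function(theta) {
    p <- unpack_theta(theta, design, layout)
    ct <- corr_transform(p$y, J)
    sigma <- exp(p$ls)
    Lsig <- sigma * ct$L
    if (any(diag(Lsig) <= 1e-12)) return(theta)
    Sinv <- crossprod(forwardsolve(Lsig, diag(J)))
    hmat <- p$h
    w <- colSums(Sinv)
    u <- sum(Sinv)
    g <- as.numeric(hmat %*% w) # 1' Sinv h_i per hour
    Tv <- p$T; Dv <- p$D
    for (t in seq_len(24)) {
      I <- which(hour_T == t - 1)
      if (!length(I)) next
      prec <- 1 + length(I) * u
      shift <- rnorm(1, (sum(g[I]) - Tv[t]) / prec, sqrt(1 / prec))
      Tv[t] <- Tv[t] + shift
      hmat[I, ] <- hmat[I, ] - shift
      g[I] <- g[I] - shift * u
    }
    for (d in seq_len(7)) {
      I <- which(hour_D == d - 1)
      if (!length(I)) next
      prec <- 1 + length(I) * u
      shift <- rnorm(1, (sum(g[I]) - Dv[d]) / prec, sqrt(1 / prec))
      Dv[d] <- Dv[d] + shift
      hmat[I, ] <- hmat[I, ] - shift
      g[I] <- g[I] - shift * u
    }
    FPv <- p$FP
    for (f in seq_len(3)) {
      M <- FP_mask[[f]]
      MS <- M %*% Sinv
      prec <- 1 + sum(MS * M)
      if (prec <= 1) next
      lin <- sum((hmat %*% Sinv) * M)
      shift <- rnorm(1, (lin - FPv[f]) / prec, sqrt(1 / prec))
      FPv[f] <- FPv[f] + shift
      hmat <- hmat - shift * M
    }
    theta[layout$idx$T] <- Tv
    theta[layout$idx$D] <- Dv
    theta[layout$idx$FP] <- FPv
    theta[layout$idx$h] <- as.numeric(hmat)
    theta
  }

  # The full conditional of (log sigma, y) given h is cov_subtarget with
  # S = crossprod(h) held fixed: sigma and R enter the joint only through
  # the h-likelihood and their own priors. A cheap Metropolis-within-Gibbs
  # sweep over these 15-odd coordinates therefore mixes the covariance
  # block independently of the trajectory sampler.
  cov_idx <- c(layout$idx$ls, layout$idx$y)
  cov_cond <- function(theta) {
    h <- matrix(theta[layout$idx$h], H, J)
    S <- crossprod(h)
    function(v) cov_subtarget(v[seq_len(J)], v[-seq_len(J)], S, H, J)
  }

  # Vectorized single-site Metropolis sweep over the random effects: given
  # the covariance and the other stations' effects, the coordinates
  # h[, j] of different hours are conditionally independent, so a whole
  # station column is proposed and accepted elementwise in one pass.
  cells_of <- lapply(seq_len(J), function(j) which(design$station == j))
  h_sweep <- function(theta, h_scales) {
    p <- unpack_theta(theta, design, layout)
    ct <- corr_transform(p$y, J)
    sigma <- exp(p$ls)
    Lsig <- sigma * ct$L
    Sinv <- crossprod(forwardsolve(Lsig, diag(J)))
    b <- design$log_tau + p$T[Ti] + p$D[Di] + p$FP[Fi]
    hmat <- p$h
    acc <- matrix(0, H, J)
    for (j in seq_len(J)) {
      sel <- cells_of[[j]]
      i_sel <- design$hour[sel]
      delta <- rnorm(H) * h_scales[, j]
      q <- as.numeric(hmat %*% Sinv[, j])
      dlp <- -(delta * q + 0.5 * delta^2 * Sinv[j, j])
      hj <- hmat[, j]
      dpois <- numeric(H)
      dpois[i_sel] <- design$V[sel] * delta[i_sel] -
        exp(b[sel]) * (exp(hj[i_sel] + delta[i_sel]) - exp(hj[i_sel]))
      dlp <- dlp + dpois
      ok <- is.finite(dlp) & (log(runif(H)) < dlp)
      hmat[ok, j] <- hj[ok] + delta[ok]
      acc[, j] <- as.numeric(ok)
    }
    theta[layout$idx$h] <- as.numeric(hmat)
    list(theta = theta, acc = acc)
  }

  # Blocked per-hour proposal shaped by the current random-effect
  # covariance: delta_i = s_i * C z_i with C C' = Sigma. Hours are
  # conditionally independent, so all hours are proposed and accepted
  # elementwise in one vectorized pass; the shaped proposal moves along the
  # correlated directions that single-site updates traverse slowly.
  h_block_sweep <- function(theta, s) {
    p <- unpack_theta(theta, design, layout)
    ct <- corr_transform(p$y, J)
    sigma <- exp(p$ls)
    Lsig <- sigma * ct$L # lower, Lsig %*% t(Lsig) = Sigma
    Sinv <- crossprod(forwardsolve(Lsig, diag(J)))
    b <- design$log_tau + p$T[Ti] + p$D[Di] + p$FP[Fi]
    hmat <- p$h
    z <- matrix(rnorm(H * J), H, J)
    delta <- (z %*% t(Lsig)) * s
    q <- hmat %*% Sinv
    dmvn <- -rowSums(delta * q) - 0.5 * s^2 * rowSums(z^2)
    eh <- hmat[cell]
    dpois_cell <- design$V * delta[cell] -
      exp(b) * (exp(eh + delta[cell]) - exp(eh))
    dpois <- numeric(H)
    sums <- rowsum(dpois_cell, design$hour)
    dpois[as.integer(rownames(sums))] <- sums
    dlp <- dmvn + dpois
    ok <- is.finite(dlp) & (log(runif(H)) < dlp)
    hmat[ok, ] <- hmat[ok, , drop = FALSE] + delta[ok, , drop = FALSE]
    theta[layout$idx$h] <- as.numeric(hmat)
    list(theta = theta, acc = as.numeric(ok))
  }

  list(lp_grad = lp_grad, recenter = recenter, cat_recenter = cat_recenter,
       cov_cond = cov_cond, cov_idx = cov_idx, h_sweep = h_sweep,
       h_block_sweep = h_block_sweep, H = H, J = J, layout = layout,
       dim = layout$dim)
}

leapfrog <- function(theta, p, eps, n_steps, target, inv_mass, st) {
  g <- st$grad
  for (s in seq_len(n_steps)) {
    p <- p + 0.5 * eps * g
    theta <- theta + eps * inv_mass * p
    st <- target$lp_grad(theta)
    if (!is.finite(st$lp)) return(NULL)
    g <- st$grad
    p <- p + 0.5 * eps * g
  }
  list(theta = theta, p = p, st = st)
}

hmc_chain <- function(target, init, iterations, warmup, seed,
                      n_leapfrog = 25, accept_target = 0.8,
                      progress = FALSE) {
  with_seed(seed, {
    dim <- target$dim
    theta <- init
    inv_mass <- rep(1, dim)
    st <- target$lp_grad(theta)
    if (!is.finite(st$lp)) abort("initialization failed: non-finite log density")

    # initial step size: scale until one-step acceptance is moderate
    eps <- 0.1 / dim^0.25
    for (rep in 1:30) {
      p0 <- rnorm(dim) / sqrt(inv_mass)
      prop <- leapfrog(theta, p0, eps, 1, target, inv_mass, st)
      if (is.null(prop)) { eps <- eps / 2; next }
      a <- exp(min(0, prop$st$lp - 0.5 * sum(inv_mass * prop$p^2) -
                     (st$lp - 0.5 * sum(inv_mass * p0^2))))
      if (a < 0.3) eps <- eps / 2 else if (a > 0.95) eps <- eps * 2 else break
    }

    # dual averaging state
    da_init <- function(eps) list(mu = log(10 * eps), log_eps_bar = 0,
                                  H_bar = 0, count = 0)
    da <- da_init(eps)
    da_update <- function(da, a) {
      da$count <- da$count + 1
      gamma <- 0.05; t0 <- 10; kappa <- 0.75
      da$H_bar <- (1 - 1 / (da$count + t0)) * da$H_bar +
        (accept_target - a) / (da$count + t0)
      log_eps <- da$mu - sqrt(da$count) / gamma * da$H_bar
      w <- da$count^(-kappa)
      da$log_eps_bar <- w * log_eps + (1 - w) * da$log_eps_bar
      da$eps <- exp(log_eps)
      da
    }

    kept <- iterations - warmup
    draws <- matrix(NA_real_, kept, dim)
    lps <- numeric(kept)
    n_accept <- 0
    mass_window <- NULL
    cov_sweeps <- 25
    ncov <- length(target$cov_idx %||% integer())
    cov_scales <- rep(0.15, ncov)
    cov_acc <- numeric(ncov)
    cov_try <- numeric(ncov)
    h_sweeps <- 10
    h_scales <- if (!is.null(target$h_sweep)) matrix(0.3, target$H, target$J)
    h_acc <- if (!is.null(target$h_sweep)) matrix(0, target$H, target$J)
    h_try <- 0
    hb_sweeps <- 10
    hb_scales <- if (!is.null(target$h_block_sweep)) rep(0.3, target$H)
    hb_acc <- if (!is.null(target$h_block_sweep)) numeric(target$H)
    hb_try <- 0
    w_lo <- max(2, floor(0.20 * warmup))
    # two mass-matrix updates: mid-warmup and late-warmup
    w_updates <- unique(c(max(3, floor(0.5 * warmup)),
                          max(4, floor(0.85 * warmup))))

    for (it in seq_len(iterations)) {
      L <- sample(max(1, floor(0.6 * n_leapfrog)):n_leapfrog, 1)
      p0 <- rnorm(dim) / sqrt(inv_mass)
      H0 <- -st$lp + 0.5 * sum(inv_mass * p0^2)
      prop <- leapfrog(theta, p0, eps, L, target, inv_mass, st)
      if (is.null(prop)) {
        a <- 0
      } else {
        H1 <- -prop$st$lp + 0.5 * sum(inv_mass * prop$p^2)
        a <- exp(min(0, H0 - H1))
        if (runif(1) < a) {
          theta <- prop$theta
          st <- prop$st
        }
      }

      moved <- FALSE
      if (!is.null(target$recenter)) {
        theta <- target$recenter(theta)
        moved <- TRUE
      }
      if (!is.null(target$cat_recenter)) {
        theta <- target$cat_recenter(theta)
        moved <- TRUE
      }
      if (!is.null(target$cov_cond)) {
        f <- target$cov_cond(theta)
        v <- theta[target$cov_idx]
        flp <- f(v)
        for (sw in seq_len(cov_sweeps)) {
          for (k in seq_along(v)) {
            prop <- v
            prop[k] <- prop[k] + rnorm(1) * cov_scales[k]
            plp <- f(prop)
            cov_try[k] <- cov_try[k] + 1
            if (is.finite(plp) && log(runif(1)) < plp - flp) {
              v <- prop; flp <- plp; cov_acc[k] <- cov_acc[k] + 1
            }
          }
        }
        theta[target$cov_idx] <- v
        moved <- TRUE
        if (it <= warmup && it %% 25 == 0) {
          rate <- cov_acc / pmax(cov_try, 1)
          cov_scales <- cov_scales * exp(2 * (rate - 0.44))
          cov_acc[] <- 0; cov_try[] <- 0
        }
      }
      if (!is.null(target$h_sweep)) {
        for (sw in seq_len(h_sweeps)) {
          hs <- target$h_sweep(theta, h_scales)
          theta <- hs$theta
          h_acc <- h_acc + hs$acc
        }
        h_try <- h_try + h_sweeps
        moved <- TRUE
        if (it <= warmup && it %% 25 == 0) {
          rate <- h_acc / h_try
          h_scales <- h_scales * exp(2 * (rate - 0.44))
          h_scales <- pmin(pmax(h_scales, 1e-3), 10)
          h_acc[] <- 0; h_try <- 0
        }
      }
      if (!is.null(target$h_block_sweep)) {
        for (sw in seq_len(hb_sweeps)) {
          hb <- target$h_block_sweep(theta, hb_scales)
          theta <- hb$theta
          hb_acc <- hb_acc + hb$acc
        }
        hb_try <- hb_try + hb_sweeps
        moved <- TRUE
        if (it <= warmup && it %% 25 == 0) {
          rate <- hb_acc / hb_try
          # blocked J-dim proposals target a lower acceptance than scalar ones
          hb_scales <- pmin(pmax(hb_scales * exp(2 * (rate - 0.3)), 1e-3), 10)
          hb_acc[] <- 0; hb_try <- 0
        }
      }
      if (moved) st <- target$lp_grad(theta)

      if (it <= warmup) {
        da <- da_update(da, a)
        eps <- da$eps
        if (it > w_lo) mass_window <- rbind(mass_window, theta)
        if (it %in% w_updates && !is.null(mass_window) &&
            nrow(mass_window) > 10) {
          v <- apply(mass_window, 2, var)
          nm <- nrow(mass_window)
          # Stan-style regularization toward unit scale
          inv_mass <- nm / (nm + 5) * v + 1e-3 * 5 / (nm + 5)
          inv_mass[inv_mass <= 0 | !is.finite(inv_mass)] <- 1e-3
          eps <- exp(da$log_eps_bar)
          da <- da_init(eps)
          mass_window <- NULL
        }
        if (it == warmup) eps <- exp(da$log_eps_bar)
      } else {
        n_accept <- n_accept + a
        draws[it - warmup, ] <- theta
        lps[it - warmup] <- st$lp
      }
    }
    list(draws = draws, lp = lps, eps = eps, inv_mass = inv_mass,
         accept_rate = n_accept / kept)
  })
}
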