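#' Fit the hierarchical Poisson call-rate model by MCMC
#'
#' Samples the posterior of the model evaluated by [log_joint()] using the
#' package's Hamiltonian Monte Carlo sampler (leapfrog integrator,
#' dual-averaging step-size adaptation and diagonal mass-matrix estimation
#' during warmup). The default configuration is three chains of 1000
#' iterations each with the first half used as warmup.
#'
#' @param design An `aas_design` from [encode_design()].
#' @param chains Number of chains (default 3).
#' @param iterations Iterations per chain including warmup (default 1000).
#' @param warmup Warmup iterations per chain (default `iterations / 2`).
#' @param seed Root seed; chain `c` uses `seed + c - 1`.
#' @param n_leapfrog Maximum leapfrog steps per proposal (jittered
#'   per-iteration between 60% and 100% of this).
#' @param init_r Initial values are drawn uniformly from
#'   `(-init_r, init_r)` on the unconstrained scale (random effects start
#'   at one tenth of that spread).
#' @param progress Print a line as each chain finishes.
#' @return An object of class `aas_fit` with elements `draws` (matrix of
#'   posterior draws on the natural scale, named columns `T[k]`, `D[k]`,
#'   `FP[k]`, `sigma_h[station]`, `R[a,b]`, `h[i,j]`, `lp__`), `chain` and
#'   `iteration` index vectors, the `design`, and sampler metadata.
#' @export
fit_call_model <- function(design, chains = 3, iterations = 1000,
                           warmup = floor(iterations / 2), seed = 1L,
                           n_leapfrog = 50, init_r = 1, progress = FALSE) {
  stopifnot(inherits(design, "aas_design"))
  if (chains < 1 || iterations <= warmup) {
    abort("need chains >= 1 and iterations > warmup")
  }
  target <- make_target(design)
  layout <- target$layout
  J <- design$J

  res <- purrr::map(seq_len(chains), function(ch) {
    init <- with_seed(seed + 1000L * ch, {
      x <- runif(target$dim, -init_r, init_r)
      x[layout$idx$h] <- x[layout$idx$h] * 0.1
      x[layout$idx$ls] <- x[layout$idx$ls] * 0.5 - 0.5
      x
    })
    out <- hmc_chain(target, init, iterations, warmup, seed = seed + ch - 1L,
                     n_leapfrog = n_leapfrog)
    if (progress) {
      message(sprintf("chain %d: accept %.2f, step size %.3g",
                      ch, out$accept_rate, out$eps))
    }
    out
  })

  kept <- iterations - warmup
  draws_un <- do.call(rbind, purrr::map(res, "draws"))
  lp <- unlist(purrr::map(res, "lp"))

  # transform to natural scale and name columns
  nat <- transform_draws(draws_un, design, layout)
  draws <- cbind(nat, `lp__` = lp)
  structure(list(
    draws = draws,
    chain = rep(seq_len(chains), each = kept),
    iteration = rep(seq_len(kept), chains),
    design = design,
    chains = chains, iterations = iterations, warmup = warmup, seed = seed,
    accept_rate = purrr::map_dbl(res, "accept_rate"),
    step_size = purrr::map_dbl(res, "eps")
  ), class = "aas_fit")
}

transform_draws <- function(draws_un, design, layout) {
  J <- design$J
  m <- J * (J - 1) / 2
  ndraw <- nrow(draws_un)
  Tm <- draws_un[, layout$idx$T, drop = FALSE]
  Dm <- draws_un[, layout$idx$D, drop = FALSE]
  Fm <- draws_un[, layout$idx$FP, drop = FALSE]
  Sg <- exp(draws_un[, layout$idx$ls, drop = FALSE])
  colnames(Tm) <- sprintf("T[%d]", 1:24)
  colnames(Dm) <- sprintf("D[%d]", 1:7)
  colnames(Fm) <- sprintf("FP[%d]", 1:3)
  colnames(Sg) <- sprintf("sigma_h[%s]", design$stations)
  Rm <- NULL
  if (m > 0) {
    pairs <- which(upper.tri(diag(J)), arr.ind = TRUE)
    pairs <- pairs[order(pairs[, "col"], pairs[, "row"]), , drop = FALSE]
    Rm <- t(apply(draws_un[, layout$idx$y, drop = FALSE], 1, function(y) {
      L <- corr_transform(y, J)$L
      R <- tcrossprod(L)
      R[upper.tri(R)] # column-major upper triangle, matching `pairs` ordering
    }))
    Rm <- matrix(Rm, nrow = ndraw)
    colnames(Rm) <- sprintf("R[%s,%s]", design$stations[pairs[, "row"]],
                            design$stations[pairs[, "col"]])
  }
  Hm <- draws_un[, layout$idx$h, drop = FALSE]
  hn <- expand.grid(i = seq_len(design$H), j = seq_len(design$J))
  colnames(Hm) <- sprintf("h[%d,%s]", hn$i, design$stations[hn$j])
  cbind(Tm, Dm, Fm, Sg, Rm, Hm)
}

#' Extract posterior draws of the station correlation matrix
#'
#' @param fit An `aas_fit`.
#' @return A 3-d array `J x J x draws` of correlation matrices.
#' @export
correlation_draws <- function(fit) {
  stopifnot(inherits(fit, "aas_fit"))
  J <- fit$design$J
  ids <- fit$design$stations
  nd <- nrow(fit$draws)
  arr <- array(NA_real_, c(J, J, nd), dimnames = list(ids, ids, NULL))
  pairs <- which(upper.tri(diag(J)), arr.ind = TRUE)
  cols <- sprintf("R[%s,%s]", ids[pairs[, "row"]], ids[pairs[, "col"]])
  for (d in seq_len(nd)) {
    R <- diag(J)
    R[pairs] <- fit$draws[d, cols]
    R[lower.tri(R)] <- t(R)[lower.tri(R)]
    arr[, , d] <- R
  }
  arr
}

#' @export
print.aas_fit <- function(x, ...) {
  cat(sprintf("<aas_fit> %d chains x %d kept draws; %d cells (%d stations x %d hours)\n",
              x$chains, x$iterations - x$warmup, x$design$n, x$design$J,
              x$design$H))
  cat(sprintf("  mean acceptance %.2f; step sizes %s\n",
              mean(x$accept_rate), paste(signif(x$step_size, 3), collapse = ", ")))
  invisible(x)
}

#' Tidy posterior summaries of a fitted call-rate model
#'
#' One row per (non-random-effect) parameter with posterior mean, median,
#' SD, central 90% interval, split R-hat and effective sample size.
#'
#' @param x An `aas_fit`.
#' @param pars Regular expression selecting parameters (default: everything
#'   except the hour-level random effects `h`).
#' @param ... Unused.
#' @return A tibble with columns `term`, `mean`, `median`, `sd`, `q5`,
#'   `q95`, `rhat`, `ess`.
#' @exportS3Method generics::tidy
tidy.aas_fit <- function(x, pars = "^(T|D|FP|sigma_h|R)\\[", ...) {
  cols <- grep(pars, colnames(x$draws), value = TRUE)
  diag_tbl <- convergence(x, pars = pars)
  purrr::map_dfr(cols, function(cn) {
    v <- x$draws[, cn]
    tibble(term = cn, mean = mean(v), median = median(v), sd = sd(v),
           q5 = quantile(v, 0.05, names = FALSE),
           q95 = quantile(v, 0.95, names = FALSE))
  }) %>%
    left_join(diag_tbl[, c("term", "rhat", "ess")], by = "term")
}

#' @rdname tidy.aas_fit
#' @exportS3Method generics::glance
glance.aas_fit <- function(x, ...) {
  conv <- convergence(x)
  tibble(
    chains = x$chains,
    iterations = x$iterations,
    warmup = x$warmup,
    draws = nrow(x$draws),
    max_rhat = max(conv$rhat, na.rm = TRUE),
    min_ess = min(conv$ess, na.rm = TRUE),
    converged = all(conv$rhat < 1.05, na.rm = TRUE),
    mean_accept = mean(x$accept_rate),
    mean_lp = mean(x$draws[, "lp__"])
  )
}
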