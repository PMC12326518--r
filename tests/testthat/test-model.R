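test_that("the LKJ(1) density is the uniform density over correlation matrices", {
  expect_equal(lkj_log_density(matrix(c(1, .3, .3, 1), 2)), -log(2))
  expect_equal(lkj_log_density(matrix(c(1, -.77, -.77, 1), 2)), -log(2))
  set.seed(4)
  vals3 <- replicate(5, lkj_log_density(random_corr(3)))
  expect_true(all(abs(vals3 - vals3[1]) < 1e-10))
  # matches -log(volume of the 3x3 elliptope), pi^2 / 2
  expect_equal(vals3[1], log(2 / pi^2), tolerance = 1e-10)
  # Monte-Carlo volume estimate agrees (fraction of the [-1,1]^3 cube that
  # is a valid correlation matrix, times the cube volume 8)
  set.seed(9)
  z <- matrix(runif(3 * 200000, -1, 1), ncol = 3)
  ok <- (1 + 2 * z[, 1] * z[, 2] * z[, 3] - z[, 1]^2 - z[, 2]^2 - z[, 3]^2) > 0
  vol_mc <- 8 * mean(ok)
  se <- 8 * sd(ok) / sqrt(length(ok))
  expect_true(abs(exp(-vals3[1]) - vol_mc) < 3 * se)
  # higher dimension: still constant, matching the closed-form constant
  vals5 <- replicate(5, lkj_log_density(random_corr(5)))
  expect_true(all(abs(vals5 - oracle_lkj1_const(5)) < 1e-10))
})

test_that("the partial-correlation transform round-trips", {
  set.seed(6)
  for (d in c(2, 3, 5)) {
    R <- random_corr(d)
    z <- aascall:::cpc_from_R(R)
    L <- aascall:::chol_from_cpc(z, d)
    expect_equal(tcrossprod(L), R, tolerance = 1e-10)
    y <- atanh(z)
    expect_equal(aascall:::corr_transform(y, d)$L, L, tolerance = 1e-10)
  }
})

test_that("the unit-mean cell has Poisson term exactly -1", {
  hc <- flat_design(1) %>% dplyr::mutate(V = 1L)
  design <- encode_design(hc)
  params <- flat_params(1, sigma_h = 1)
  params$h <- matrix(0, 1, 1)
  lj <- log_joint(params, design)
  # oracle assembled term by term: Poisson log pmf at mu = 1 is exactly -1
  expected <- -1 +
    sum(dnorm(rep(0, 34), log = TRUE)) + # 24 T + 7 D + 3 FP priors at zero
    dexp(1, log = TRUE) +                # sigma_h = 1
    dnorm(0, 0, 1, log = TRUE)           # h = 0 under sigma = 1 (J = 1)
  expect_equal(lj, expected, tolerance = 1e-12)
})

test_that("log_joint equals the brute-force summation oracle", {
  set.seed(10)
  cfg <- sim_config(n_stations = 3, n_hours = 20, seed = 3)
  hc <- simulate_hour_counts(true_parameters(cfg),
                             make_design(cfg, tau = runif(60, 0.3, 1)),
                             seed = 2)
  design <- encode_design(hc)
  for (rep in 1:25) {
    p <- flat_params(3, sigma_h = 1)
    p$T <- rnorm(24); p$D <- rnorm(7); p$FP <- rnorm(3)
    p$sigma_h <- rexp(3) + 0.1
    p$R <- random_corr(3)
    p$h <- matrix(rnorm(design$H * design$J, 0, 0.5), design$H, design$J)
    lj <- log_joint(p, design)
    expect_equal(lj, oracle_log_joint(p, design), tolerance = 1e-8)
  }
})

test_that("log_joint is invariant to permuting the hour order", {
  set.seed(12)
  cfg <- sim_config(n_stations = 2, n_hours = 15, seed = 5)
  hc <- simulate_hour_counts(true_parameters(cfg), make_design(cfg, tau = 1),
                             seed = 4)
  design <- encode_design(hc)
  p <- flat_params(2, sigma_h = 0.7, R = matrix(c(1, .4, .4, 1), 2))
  p$h <- matrix(rnorm(design$H * 2, 0, 0.5), design$H, 2)
  lj1 <- log_joint(p, design)
  # shuffling the rows of the input table leaves the density unchanged
  hc_shuffled <- hc[sample(nrow(hc)), ]
  expect_equal(log_joint(p, encode_design(hc_shuffled)), lj1,
               tolerance = 1e-12)
  # relabelling the hours (a permutation of the time axis, with the h rows
  # and covariates carried along) also leaves the density unchanged, since
  # hours are exchangeable given their covariates
  perm <- sample(design$H)
  hc2 <- hc %>%
    dplyr::mutate(hour_index = match(hour_start, sort(unique(hour_start))),
                  hour_start = sort(unique(hc$hour_start))[perm[hour_index]]) %>%
    dplyr::select(-hour_index)
  p2 <- p
  p2$h[perm, ] <- p$h
  expect_equal(log_joint(p2, encode_design(hc2)), lj1, tolerance = 1e-12)
})

test_that("invalid parameter shapes and covariances are rejected", {
  hc <- flat_design(4) %>% dplyr::mutate(V = 1L)
  design <- encode_design(hc)
  p <- flat_params(1, sigma_h = 1)
  p$h <- matrix(0, 4, 1)
  bad <- p
  bad$sigma_h <- 0
  expect_error(log_joint(bad, design), "positive")
  badR <- flat_params(2, sigma_h = 1,
                      R = matrix(c(1, 1.2, 1.2, 1), 2))
  expect_error(check_parameters <- aascall:::check_parameters(badR), "positive|\\[-1")
})

test_that("encode_design validates and restricts to complete hours", {
  cfg <- sim_config(n_stations = 2, n_hours = 10)
  hc <- simulate_hour_counts(true_parameters(cfg), make_design(cfg, tau = 1),
                             seed = 1)
  expect_error(encode_design(dplyr::bind_rows(hc, hc[1, ])), "duplicate")
  expect_error(encode_design(dplyr::mutate(hc, tau = 0)), "tau")
  # drop one station-hour: that hour disappears under complete-case
  d2 <- encode_design(hc[-1, ], complete_hours = TRUE)
  expect_equal(d2$H, 9)
  d3 <- encode_design(hc[-1, ], complete_hours = FALSE)
  expect_equal(d3$H, 10)
  expect_equal(d3$n, 19)
  # index mappings
  expect_equal(unique(hc$T_index[format(hc$hour_start, "%H") == "19"]), 19L)
})

test_that("a small fit produces valid draws, diagnostics and summaries", {
  cfg <- sim_config(n_stations = 2, n_hours = 24, sigma_h = 0.3, seed = 8)
  hc <- simulate_hour_counts(true_parameters(cfg), make_design(cfg, tau = 1),
                             seed = 3)
  design <- encode_design(hc)
  fit <- fit_call_model(design, chains = 2, iterations = 200, seed = 5,
                        n_leapfrog = 15)
  expect_s3_class(fit, "aas_fit")
  expect_equal(nrow(fit$draws), 200)
  # stored correlation draws are valid correlation matrices
  arr <- correlation_draws(fit)
  for (k in seq(1, dim(arr)[3], by = 37)) {
    R <- arr[, , k]
    expect_equal(R, t(R), tolerance = 1e-8)
    expect_equal(diag(R), setNames(rep(1, 2), rownames(R)), tolerance = 1e-8)
    expect_gte(min(eigen(R, only.values = TRUE)$values), -1e-8)
  }
  expect_true(all(fit$draws[, "sigma_h[LS1]"] > 0))
  # reproducibility
  fit2 <- fit_call_model(design, chains = 2, iterations = 200, seed = 5,
                         n_leapfrog = 15)
  expect_identical(fit$draws, fit2$draws)
  # tidy/glance surfaces
  td <- tidy(fit)
  expect_true(all(c("term", "mean", "rhat", "ess") %in% names(td)))
  expect_equal(nrow(td), 24 + 7 + 3 + 2 + 1)
  g <- glance(fit)
  expect_equal(g$draws, 200)
  expect_true(is.finite(g$mean_lp))
})

test_that("null simulated data recover near-zero within-factor contrasts", {
  cfg <- sim_config(n_stations = 2, n_hours = 96, sigma_h = 0.1,
                    T_effects = rep(1, 24), D_effects = rep(0, 7),
                    FP_effects = rep(0, 3), seed = 13)
  hc <- simulate_hour_counts(true_parameters(cfg), make_design(cfg, tau = 1),
                             seed = 14)
  fit <- fit_call_model(encode_design(hc), chains = 2, iterations = 400,
                        seed = 2, n_leapfrog = 20)
  contrast <- fit$draws[, "T[20]"] - fit$draws[, "T[8]"]
  expect_lt(abs(mean(contrast)), 2 * sd(contrast))
})

test_that("convergence flags deliberately broken chains", {
  cfg <- sim_config(n_stations = 2, n_hours = 12, seed = 4)
  hc <- simulate_hour_counts(true_parameters(cfg), make_design(cfg, tau = 1),
                             seed = 1)
  design <- encode_design(hc)
  # chains far apart with almost no adaptation cannot converge
  fit_bad <- fit_call_model(design, chains = 3, iterations = 16, warmup = 8,
                            seed = 1, n_leapfrog = 2, init_r = 6)
  conv <- convergence(fit_bad, pars = "^(T|D)\\[")
  expect_gt(max(conv$rhat, na.rm = TRUE), 1.2)
  expect_false(attr(conv, "pass"))
  # single chain: R-hat unavailable
  fit_one <- fit_call_model(design, chains = 1, iterations = 30, warmup = 10,
                            seed = 1, n_leapfrog = 2)
  expect_warning(c1 <- convergence(fit_one), "2 chains")
  expect_true(all(is.na(c1$rhat)))
})

test_that("identical duplicated chains give R-hat near 1", {
  set.seed(21)
  draws <- rnorm(400)
  m <- cbind(draws, draws) # two identical "chains"
  expect_equal(aascall:::split_rhat(m), 1, tolerance = 0.02)
})

test_that("degenerate posteriors summarise to the point values", {
  R <- matrix(c(1, .5, .25, .5, 1, .5, .25, .5, 1), 3)
  stations <- c("A", "B", "C")
  ff <- fake_fit(replicate(40, R, simplify = FALSE), stations)
  g <- tibble::tibble(station_id = stations, lat = c(0, 0, 0),
                      lon = c(0, 0.002, 0.004))
  pr <- correlation_pairs(ff, g)
  expect_equal(nrow(pr), 3)
  expect_equal(pr$rho_median[order(pr$station_a, pr$station_b)],
               c(0.5, 0.25, 0.5))
  expect_equal(pr$rho_q25, pr$rho_q75)
})

test_that("effect summaries expose crepuscular structure in the truth", {
  # strongly peaked truth, sigma small: posterior medians of T peak at the
  # configured crepuscular hours
  cfg <- sim_config(n_stations = 2, n_hours = 144, sigma_h = 0.15, seed = 17)
  hc <- simulate_hour_counts(true_parameters(cfg), make_design(cfg, tau = 1),
                             seed = 18)
  fit <- fit_call_model(encode_design(hc), chains = 2, iterations = 500,
                        seed = 6, n_leapfrog = 25)
  eff <- predict_effects(fit)
  expect_setequal(unique(eff$factor), c("T", "D", "FP"))
  Tm <- eff[eff$factor == "T", ]
  crep <- Tm$level %in% c(6, 7, 8, 18, 19, 20)
  top6 <- order(Tm$median, decreasing = TRUE)[1:6]
  expect_gte(sum(top6 %in% which(crep)), 5)
  # evening peak higher than morning peak, as in the generating template
  expect_gt(Tm$median[Tm$level == 19], Tm$median[Tm$level == 7])
  # degenerate posterior: summaries equal the single draw's effects
  one <- fit
  one$draws <- fit$draws[rep(1, 10), ]
  eff1 <- predict_effects(one)
  expect_equal(eff1$median[eff1$factor == "T"],
               unname(exp(fit$draws[1, sprintf("T[%d]", 1:24)])))
})
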