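test_that("a static fish mass yields fixed proximity categories", {
  # stations at 0/150/300 m; a zero-variance walk starts at the array
  # midpoint, i.e. exactly at the middle station
  cfg <- sim_config(n_stations = 3, n_hours = 24, traj_sd_m = 0)
  geom <- make_geometry(cfg)
  traj <- simulate_fsa_trajectory(cfg, geom, seed = 1)
  prox <- traj$proximity
  mid <- geom$station_id[2]
  expect_true(all(prox$FP_index[prox$station_id == mid] == 2L))
  expect_true(all(prox$FP_index[prox$station_id != mid] == 0L))
})

test_that("proximity categories equal brute-force distance thresholding", {
  cfg <- sim_config(n_stations = 4, n_hours = 72, traj_sd_m = 60)
  geom <- make_geometry(cfg)
  traj <- simulate_fsa_trajectory(cfg, geom, seed = 3)
  joined <- dplyr::left_join(
    traj$proximity,
    dplyr::select(traj$positions, hour_index, mass = along_m),
    by = "hour_index")
  joined <- dplyr::left_join(
    joined, dplyr::select(geom, station_id, st = along_m), by = "station_id")
  d <- abs(joined$mass - joined$st)
  brute <- ifelse(d <= 20, 2L, ifelse(d <= 100, 1L, 0L))
  expect_identical(joined$FP_index, brute)
})

test_that("a persistent shift moves the nearest station along the array", {
  cfg <- sim_config(n_stations = 4, n_hours = 40, traj_sd_m = 0,
                    traj_shift = list(at_hour = 20, offset_m = 300))
  geom <- make_geometry(cfg)
  traj <- simulate_fsa_trajectory(cfg, geom, seed = 1)
  nearest <- sapply(traj$positions$along_m,
                    function(x) which.min(abs(geom$along_m - x)))
  expect_false(nearest[1] == nearest[40])
  expect_equal(traj$positions$along_m[40] - traj$positions$along_m[1], 300,
               tolerance = 1e-9)
})

test_that("the null count process is unit-mean Poisson", {
  des <- flat_design(10000)
  hc <- simulate_hour_counts(flat_params(1), des, seed = 5)
  expect_true(abs(mean(hc$V) - 1) < 3 * sqrt(1 / nrow(hc)))
  expect_true(all(hc$h == 0))
})

test_that("count moments match the Poisson-lognormal closed form", {
  sig <- 0.6
  eta <- c(T = 0.4, D = -0.2, FP = 0.3)
  params <- flat_params(1, sigma_h = sig)
  params$T[1] <- eta["T"]; params$D[1] <- eta["D"]; params$FP[1] <- eta["FP"]
  des <- flat_design(20000, tau = 0.8)
  hc <- simulate_hour_counts(params, des, seed = 8)
  m_theory <- exp(sum(eta) + sig^2 / 2)
  x <- hc$V / hc$tau
  se <- sd(x) / sqrt(length(x))
  expect_true(abs(mean(x) - m_theory) < 3 * se)
})

test_that("latent station effects carry the configured correlation", {
  R <- matrix(c(1, 0.9, 0.9, 1), 2)
  params <- flat_params(2, sigma_h = 1, R = R)
  des <- flat_design(12000, stations = c("S1", "S2"))
  hc <- simulate_hour_counts(params, des, seed = 9)
  hw <- tidyr::pivot_wider(hc[, c("station_id", "hour_index", "h")],
                           names_from = "station_id", values_from = "h")
  expect_equal(cor(hw$S1, hw$S2), 0.9, tolerance = 0.02)
})

test_that("zero counts produce an empty event table", {
  cfg <- tiny_config()
  hc <- make_design(cfg, tau = 1) %>% dplyr::mutate(V = 0L)
  out <- simulate_minute_stream(hc, cfg, seed = 2)
  expect_equal(nrow(out$events), 0)
})

test_that("per-hour event counts are conserved through minute placement", {
  cfg <- sim_config(n_stations = 2, n_hours = 12, seed = 31)
  sim <- simulate_dataset(cfg)
  recount <- sim$events %>%
    dplyr::mutate(hour_start = as.POSIXct(trunc(minute_start, "hours"),
                                          tz = "UTC")) %>%
    dplyr::count(station_id, hour_start, name = "V2")
  cmp <- dplyr::left_join(sim$hourcells, recount,
                          by = c("station_id", "hour_start")) %>%
    dplyr::mutate(V2 = dplyr::coalesce(V2, 0L))
  expect_identical(as.integer(cmp$V), as.integer(cmp$V2))
  # events never fall in interference minutes
  flagged <- sim$minutes[sim$minutes$interference, ]
  key <- function(x) paste(x$station_id, format(x$minute_start))
  expect_false(any(key(sim$events) %in% key(flagged)))
})

test_that("interference share matches the configured fraction", {
  cfg <- sim_config(n_stations = 2, n_hours = 158, interference_frac = 0.044,
                    seed = 12)
  mins <- simulate_interference(cfg, seed = 77)
  p_hat <- mean(mins$interference)
  se <- sqrt(0.044 * (1 - 0.044) / nrow(mins))
  expect_true(abs(p_hat - 0.044) < 3 * se)
})

test_that("infeasible detection density is an error", {
  cfg <- tiny_config()
  hc <- make_design(cfg, tau = 1)[1, ] %>% dplyr::mutate(V = 1801L)
  expect_error(simulate_minute_stream(hc, cfg, seed = 1), "exceed")
})

test_that("a perfect simulated classifier reproduces the true stream", {
  cfg <- sim_config(n_stations = 2, n_hours = 12, classifier_tpr = 1,
                    classifier_fp_per_min = 0, seed = 3)
  sim <- simulate_dataset(cfg)
  expect_identical(
    as.data.frame(sim$predicted[, c("station_id", "minute_start", "bin_index")]),
    as.data.frame(sim$truth[, c("station_id", "minute_start", "bin_index")]))
})

test_that("classifier sensitivity is recovered within binomial error", {
  cfg <- sim_config(n_stations = 4, n_hours = 96, classifier_tpr = 0.7,
                    classifier_fp_per_min = 0, seed = 21)
  sim <- simulate_dataset(cfg)
  n <- nrow(sim$truth)
  expect_gt(n, 1000)
  p_hat <- nrow(sim$predicted) / n
  expect_true(abs(p_hat - 0.7) < qnorm(0.975) * sqrt(0.7 * 0.3 / n))
})

test_that("a zero-sensitivity classifier yields no true positives", {
  cfg <- sim_config(n_stations = 2, n_hours = 8, classifier_tpr = 0,
                    classifier_fp_per_min = 0.1, seed = 4)
  sim <- simulate_dataset(cfg)
  key <- function(x) paste(x$station_id, format(x$minute_start), x$bin_index)
  expect_false(any(key(sim$predicted) %in% key(sim$truth)))
})

test_that("the generator is bit-reproducible for a fixed seed", {
  cfg <- sim_config(n_stations = 2, n_hours = 10, seed = 99)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$hourcells, b$hourcells)
  expect_identical(a$events, b$events)
  expect_identical(a$predicted, b$predicted)
})

test_that("the distance-kernel correlation matrix is valid and monotone", {
  cfg <- sim_config(n_stations = 6, corr_decay_m = 300)
  params <- true_parameters(cfg)
  R <- params$R
  expect_equal(R, t(R))
  expect_equal(diag(R), setNames(rep(1, 6), colnames(R)))
  expect_gte(min(eigen(R, symmetric = TRUE, only.values = TRUE)$values),
             -1e-10)
  d <- haversine_matrix(make_geometry(cfg))
  ut <- upper.tri(R)
  expect_true(all(diff(R[ut][order(d[ut])]) <= 1e-12))
})

test_that("a user-supplied correlation matrix is projected to valid form", {
  bad <- matrix(c(1, 0.95, -0.95, 0.95, 1, 0.95, -0.95, 0.95, 1), 3)
  cfg <- sim_config(n_stations = 3, R = bad)
  R <- true_parameters(cfg)$R
  expect_gte(min(eigen(R, symmetric = TRUE, only.values = TRUE)$values),
             -1e-10)
  expect_equal(unname(diag(R)), rep(1, 3))
})
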