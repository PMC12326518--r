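test_that("2-s binning keeps the earliest call per bin", {
  expect_equal(nrow(bin_events(numeric(), "LS1", "2020-02-08T10:00:00")), 0)
  ev <- bin_events(c(33.1, 33.8), "LS1", "2020-02-08T10:00:00")
  expect_equal(nrow(ev), 1)
  expect_equal(ev$bin_index, 16L) # the bin covering [32, 34) s
  expect_equal(ev$call_time, 33.1)
})

test_that("binning matches the brute-force group-by-floor oracle", {
  set.seed(14)
  times <- runif(500, 0, 60)
  ev <- bin_events(times, "S", "2020-02-08T00:00:00")
  oracle <- tapply(times, floor(times / 2), min)
  expect_equal(ev$bin_index, as.integer(names(oracle)))
  expect_equal(ev$call_time, as.numeric(oracle))
})

test_that("out-of-range call times are dropped with a warning", {
  expect_warning(ev <- bin_events(c(5, 61, -1), "S", "2020-02-08T00:00:00"),
                 "dropping 2")
  expect_equal(nrow(ev), 1)
})

test_that("the 1-in-5 subsample picks every fifth minute from record start", {
  mins <- tibble::tibble(
    station_id = "S1",
    minute_start = as.POSIXct("2020-02-08 10:00:00", tz = "UTC") +
      60 * (0:299))
  out <- subsample_minutes(mins)
  expect_equal(sum(out$sampled), 60)
  idx <- which(out$sampled) - 1
  expect_true(all(idx %% 5 == 0))
  short <- subsample_minutes(mins[1:3, ])
  expect_equal(sum(short$sampled), 1)
})

test_that("two flags five minutes apart give one contiguous exclusion", {
  mins <- tibble::tibble(
    station_id = "S1",
    minute_start = as.POSIXct("2020-02-08 09:50:00", tz = "UTC") + 60 * (0:29),
    interference = FALSE) %>%
    subsample_minutes()
  flag_at <- as.POSIXct(c("2020-02-08 10:00:00", "2020-02-08 10:05:00"),
                        tz = "UTC")
  mins$interference[mins$minute_start %in% flag_at] <- TRUE
  out <- expand_interference(mins)
  excl <- sort(out$minute_start[out$excluded])
  expect_equal(length(excl), 10)
  expect_equal(min(excl), as.POSIXct("2020-02-08 09:58:00", tz = "UTC"))
  expect_equal(max(excl), as.POSIXct("2020-02-08 10:07:00", tz = "UTC"))
  expect_equal(as.numeric(diff(excl), units = "mins"), rep(1, 9))
})

test_that("no flags means no exclusions", {
  mins <- tibble::tibble(
    station_id = "S1",
    minute_start = as.POSIXct("2020-02-08 00:00:00", tz = "UTC") + 60 * (0:59),
    interference = FALSE) %>% subsample_minutes()
  expect_equal(sum(expand_interference(mins)$excluded), 0)
})

test_that("window expansion equals the brute-force union and is monotone", {
  set.seed(5)
  base <- tibble::tibble(
    station_id = "S1",
    minute_start = as.POSIXct("2020-02-08 00:00:00", tz = "UTC") + 60 * (0:199),
    interference = FALSE) %>% subsample_minutes()
  flags <- sort(sample(which(base$sampled), 6))
  mins <- base
  mins$interference[flags] <- TRUE
  out <- expand_interference(mins)
  brute <- rep(FALSE, 200)
  for (f in flags) brute[max(1, f - 2):min(200, f + 2)] <- TRUE
  expect_identical(out$excluded, brute)
  # adding one more flag never shrinks the exclusion set
  mins2 <- mins
  extra <- setdiff(which(base$sampled), flags)[1]
  mins2$interference[extra] <- TRUE
  out2 <- expand_interference(mins2)
  expect_true(all(out2$excluded[out$excluded]))
})

test_that("effort is the observed fraction of the hour", {
  mk <- function(n_obs) {
    tibble::tibble(
      station_id = "S1",
      minute_start = as.POSIXct("2020-02-08 10:00:00", tz = "UTC") + 60 * (0:59),
      observed = c(rep(TRUE, n_obs), rep(FALSE, 60 - n_obs)))
  }
  expect_equal(compute_effort(mk(60))$tau, 1.0)
  expect_equal(compute_effort(mk(45))$tau, 0.75)
  expect_message(out <- compute_effort(mk(0)), "no observable")
  expect_equal(nrow(out), 0) # fully excluded hour is absent, not tau = 0
})

test_that("hourly aggregation counts, normalises and conserves events", {
  mins <- tibble::tibble(
    station_id = "S1",
    minute_start = as.POSIXct("2020-02-08 10:00:00", tz = "UTC") + 60 * (0:59),
    observed = rep(c(TRUE, FALSE), each = 30))
  empty <- tibble::tibble(station_id = character(),
                          minute_start = as.POSIXct(character(), tz = "UTC"),
                          bin_index = integer())
  hc0 <- aggregate_hourly(empty, mins)
  expect_equal(hc0$V, 0L)
  expect_equal(hc0$rate, 0)
  set.seed(3)
  ev <- tibble::tibble(
    station_id = "S1",
    minute_start = sample(mins$minute_start[mins$observed], 30, replace = TRUE),
    bin_index = integer(30))
  ev$bin_index <- as.integer(ave(seq_len(30), format(ev$minute_start),
                                 FUN = seq_along)) - 1L
  hc <- aggregate_hourly(ev, mins)
  expect_equal(hc$V, 30L)
  expect_equal(hc$tau, 0.5)
  expect_equal(hc$rate, 60)
  # re-running on identical inputs is a no-op
  expect_identical(hc, aggregate_hourly(ev, mins))
})

test_that("events in non-observed minutes are a pipeline violation", {
  mins <- tibble::tibble(
    station_id = "S1",
    minute_start = as.POSIXct("2020-02-08 10:00:00", tz = "UTC") + 60 * (0:59),
    observed = c(FALSE, rep(TRUE, 59)))
  ev <- tibble::tibble(station_id = "S1",
                       minute_start = mins$minute_start[1], bin_index = 0L)
  expect_error(aggregate_hourly(ev, mins), "non-observed")
  expect_equal(nrow(filter_events_observed(ev, mins)), 0)
})

test_that("pipeline conservation holds end to end on synthetic data", {
  cfg <- sim_config(n_stations = 2, n_hours = 24, seed = 6)
  sim <- simulate_dataset(cfg)
  mm <- sim$minutes %>% subsample_minutes() %>% expand_interference()
  ev <- filter_events_observed(sim$events, mm)
  hc <- aggregate_hourly(ev, mm)
  expect_equal(sum(hc$V), nrow(ev))
  expect_true(all(hc$tau > 0 & hc$tau <= 1))
  expect_true(all(hc$rate == hc$V / hc$tau))
})

test_that("MaxN counts map to the video-census abundance categories", {
  expect_identical(categorize_maxn(c(0, 1, 2, 7, 10, 11, 100, 101, 150)),
                   c(0L, 1L, 2L, 2L, 2L, 3L, 3L, 4L, 4L))
  expect_error(categorize_maxn(-1), "nonnegative")
})

test_that("composite proximity takes the most informative source", {
  hr <- as.POSIXct("2020-02-08 10:00:00", tz = "UTC")
  obs <- tibble::tibble(
    station_id = c("A", "A", "B", "C", "C"),
    hour_start = hr,
    distance_class = c("within20", "beyond", "within100", "beyond", "beyond"))
  out <- composite_proximity(obs)
  expect_equal(out$FP_index[out$station_id == "A"], 2L)
  expect_equal(out$FP_index[out$station_id == "B"], 1L)
  expect_equal(out$FP_index[out$station_id == "C"], 0L)
  expect_error(composite_proximity(dplyr::mutate(obs, distance_class = "x")),
               "distance_class")
})
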