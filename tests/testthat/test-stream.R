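fast_stream <- function(schedule, profiles, start, end, seed) {
  # tiny frames: arrival statistics are what matters here, not image content
  generate_event_stream(schedule, profiles, start, end, "s", seed,
                        image_side = 8L, pixel_scale = 16)
}

test_that("stream generation honours rates, bounds and fog intervals", {
  d0 <- as.POSIXct("2024-05-01", tz = "UTC")
  profs <- list(poaceae = default_profiles()$poaceae,
                droplet = droplet_profile())
  empty <- fast_stream(episode_schedule(
    tibble::tibble(taxon = "poaceae", start = d0, end = d0 + 86400, rate = 0)),
    profs, d0, d0 + 86400, 1)
  expect_identical(nrow(empty$events), 0L)
  expect_identical(empty$manifest$n_events, 0L)

  expect_error(episode_schedule(tibble::tibble(taxon = "poaceae", start = d0,
                                               end = d0 + 3600, rate = -1)),
               class = "holopollen_invalid_parameter")

  fog <- tibble::tibble(start = d0 + 6 * 3600, end = d0 + 9 * 3600, rate = 20)
  st <- fast_stream(episode_schedule(
    tibble::tibble(taxon = "poaceae", start = d0, end = d0 + 86400, rate = 2),
    fog), profs, d0, d0 + 86400, 9)
  ev <- st$events
  expect_true(all(ev$timestamp >= d0 & ev$timestamp < d0 + 86400))
  drop_ts <- ev$timestamp[ev$true_label == "droplet"]
  expect_gt(length(drop_ts), 0)
  expect_true(all(drop_ts >= fog$start & drop_ts < fog$end))
  expect_silent(validate_events(ev))
})

test_that("hourly arrival counts behave like a Poisson process", {
  d0 <- as.POSIXct("2024-05-01", tz = "UTC")
  profs <- list(poaceae = default_profiles()$poaceae)
  sched <- episode_schedule(
    tibble::tibble(taxon = "poaceae", start = d0, end = d0 + 86400, rate = 10))
  counts <- vapply(1:200, function(s)
    nrow(fast_stream(sched, profs, d0, d0 + 86400, s)$events), numeric(1))
  # mean of 200 replicates of Poisson(240)
  expect_lt(abs(mean(counts) - 240), 3 * sqrt(240 / 200))
  # aggregate goodness of fit of the per-replicate totals
  brk <- stats::qpois(seq(0, 1, by = 0.125), 240)
  brk[1] <- -Inf; brk[length(brk)] <- Inf
  obs <- table(cut(counts, brk))
  pr <- diff(stats::ppois(brk, 240))
  gof <- stats::chisq.test(as.vector(obs), p = pr / sum(pr))
  expect_gt(gof$p.value, 0.01)
})

test_that("manual-trap emulation recovers the efficiency factor", {
  truth <- daily_series(rep(c(0, 40, 120), 10), source = "true")
  exact <- emulate_manual_series(truth, efficiency = 1, noise_dispersion = 0)
  expect_equal(exact$value, truth$value)
  expect_identical(exact$source[1], "manual")
  zero <- emulate_manual_series(daily_series(rep(0, 10), source = "true"),
                                efficiency = 3, noise_dispersion = 0.5)
  expect_true(all(zero$value == 0))
  expect_error(emulate_manual_series(truth, efficiency = 0),
               class = "holopollen_invalid_parameter")

  long <- daily_series(rep(50, 5000), source = "true")
  noisy <- emulate_manual_series(long, efficiency = 2, noise_dispersion = 0.2,
                                 rng_seed = 11)
  expect_lt(abs(sum(noisy$value) / sum(long$value) - 2), 0.1)
})
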