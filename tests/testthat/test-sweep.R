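# Small synthetic campaign shared by the sweep tests: 21 days, a 10-day
# grass season, perfect-information predictions jittered into a spread of
# confidences so thresholds bite.
sweep_fixture <- function(seed = 5) {
  d0 <- as.POSIXct("2024-05-01", tz = "UTC")
  withr::with_seed(seed, {
    n <- 400
    ts <- d0 + sort(c(runif(n * 0.8, 4 * 86400, 14 * 86400),
                      runif(n * 0.2, 0, 21 * 86400)))
    ev <- tibble::tibble(event_id = sprintf("e%04d", seq_along(ts)),
                         timestamp = ts, site = "s",
                         true_label = "poaceae")
    conf <- runif(nrow(ev), 0.34, 1)
    preds <- tibble::tibble(
      event_id = ev$event_id,
      probs = lapply(conf, function(cc)
        c(poaceae = cc, betula = (1 - cc) * 0.6, droplet = (1 - cc) * 0.4)),
      confidence = conf)
    lab <- ev
    lab$label <- lab$true_label
    counts <- aggregate_counts(lab, "daily", "poaceae", start = d0,
                               end = d0 + 21 * 86400)
    truth <- counts_to_concentration(counts, 0.05, "daily", site = "s",
                                     taxon = "poaceae", source = "true")
    manual <- emulate_manual_series(truth, efficiency = 1.5,
                                    noise_dispersion = 0)
    list(events = ev, preds = preds, manual = manual)
  })
}

test_that("threshold sweeps have consistent shape and monotonicity", {
  fx <- sweep_fixture()
  grid <- c(0, 0.4, 0.6, 0.8, 0.95)
  curve <- threshold_sweep(fx$preds, fx$events, fx$manual, grid, "poaceae",
                           sample_flow = 0.05)
  expect_identical(nrow(curve), length(grid))
  expect_true(all(diff(curve$counts_retained) <= 0))
  s <- curve$scaling[!is.na(curve$scaling)]
  expect_true(all(diff(s) >= 0))  # fixed manual totals, shrinking automatic
  expect_error(threshold_sweep(fx$preds, fx$events, fx$manual, c(0.5, 0.1),
                               "poaceae"),
               class = "holopollen_invalid_parameter")
})

test_that("a saturating threshold leaves every metric undefined", {
  fx <- sweep_fixture()
  res <- evaluate_at_threshold(fx$preds, fx$events, fx$manual, 1, "poaceae",
                               sample_flow = 0.05)
  expect_identical(res$counts_retained, 0L)
  expect_true(is.na(res$scaling))
  expect_true(is.na(res$tau))
  expect_true(is.na(res$noise_ratio))
})

test_that("perfect classification at c=0 recovers tau 1 and the efficiency", {
  fx <- sweep_fixture()
  perfect <- perfect_predictions(fx$events, c("poaceae", "betula", "droplet"))
  res <- evaluate_at_threshold(perfect, fx$events, fx$manual, 0, "poaceae",
                               sample_flow = 0.05)
  expect_equal(res$tau, 1)
  expect_equal(res$scaling, 1.5, tolerance = 1e-12)
})

test_that("cross-site envelopes bound the mean and ignore site order", {
  fx <- sweep_fixture()
  grid <- c(0, 0.5, 0.9)
  mk <- function(site, seed) {
    f <- sweep_fixture(seed)
    threshold_sweep(f$preds, f$events, f$manual, grid, "poaceae",
                    sample_flow = 0.05, site = site)
  }
  c1 <- mk("alpha", 5); c2 <- mk("beta", 6); c3 <- mk("gamma", 7)
  env <- cross_site_envelope(list(c1, c2, c3))
  expect_true(all(env$min <= env$mean + 1e-12 & env$mean <= env$max + 1e-12,
                  na.rm = TRUE))
  env_perm <- cross_site_envelope(list(c3, c1, c2))
  expect_equal(as.data.frame(env), as.data.frame(env_perm))

  single <- cross_site_envelope(list(c1))
  expect_true(all(single$min == single$mean & single$mean == single$max,
                  na.rm = TRUE))

  short <- c2[c2$threshold < 0.9, ]
  class(short) <- class(c2)
  expect_error(cross_site_envelope(list(c1, short)),
               class = "holopollen_input_error")

  two <- cross_site_envelope(list(c1, c2))
  t1 <- c1$tau[1]; t2 <- c2$tau[1]
  row <- two[two$metric == "tau" & two$threshold == 0, ]
  expect_equal(row$mean, mean(c(t1, t2)))
  expect_equal(row$min, min(t1, t2))
  expect_equal(row$max, max(t1, t2))
})

test_that("metric curves and envelopes plot without error", {
  fx <- sweep_fixture()
  curve <- threshold_sweep(fx$preds, fx$events, fx$manual, c(0, 0.5, 0.9),
                           "poaceae", sample_flow = 0.05)
  expect_s3_class(autoplot(curve), "ggplot")
  expect_s3_class(autoplot(cross_site_envelope(list(curve))), "ggplot")
  ev <- make_labelled_set(default_profiles()["poaceae"], 1, 2)
  expect_s3_class(plot_hologram(ev), "ggplot")
})
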