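tiny_config <- function(classes = c("a", "b", "c"), ...) {
  model_config(classes, image_side = 16, conv_channels = c(4L),
               fluor_hidden_units = 4L, epochs = 5L, batch_size = 8L,
               rng_seed = 3L, ...)
}

tiny_set <- function(n_per, seed) {
  profs <- list(a = default_profiles()$poaceae,
                b = default_profiles()$fraxinus,
                c = droplet_profile())
  profs <- purrr::imap(profs, function(p, nm) { p$name <- nm; p })
  make_labelled_set(profs, n_per, seed, side = 16L, scale = 8)
}

test_that("configuration invariants are enforced", {
  expect_error(model_config("one"), class = "holopollen_invalid_parameter")
  expect_error(model_config(c("a", "b"), image_side = 50,
                            conv_channels = c(8L, 16L)),
               class = "holopollen_config_error")
  expect_error(model_config(c("a", "b"), fluor_mask_prob = 1.2),
               class = "holopollen_invalid_parameter")
  expect_error(model_config(c("a", "b"), fluor_hidden_units = 0),
               class = "holopollen_invalid_parameter")
})

test_that("predictions live on the probability simplex and are deterministic", {
  m <- build_model(tiny_config())
  ev <- tiny_set(4, 21)
  pr <- predict(m, ev)
  for (p in pr$probs) {
    expect_true(all(p >= 0))
    expect_lt(abs(sum(p) - 1), 1e-6)
  }
  expect_equal(pr$confidence, vapply(pr$probs, max, numeric(1)))
  m2 <- build_model(tiny_config())
  expect_identical(predict(m2, ev), pr)  # same seed, same initial weights
})

test_that("absent fluorescence is identical to zeros plus flag 0", {
  m <- build_model(tiny_config())
  ev <- tiny_set(2, 31)
  ev_absent <- ev
  ev_absent$fluorescence <- rep(list(NULL), nrow(ev))
  ev_zero <- ev
  ev_zero$fluorescence <- rep(list(rep(0, 13)), nrow(ev))
  la <- holopollen:::model_logits(m, ev_absent)
  # the encoding contract: zeros + flag 0 is exactly the absent encoding
  enc <- holopollen:::encode_events(ev_absent, 16)
  expect_true(all(enc$fl == 0))
  enc0 <- holopollen:::encode_events(ev_zero, 16)
  expect_identical(enc0$fl[14, ], rep(1, nrow(ev)))
  lz <- holopollen:::nn_forward_cpp(m$params, enc$img, enc$fl * 0,
                                    m$config$conv_channels, 16L)
  expect_identical(la, lz)
})

test_that("batched and single-event prediction agree, order permutes outputs", {
  m <- build_model(tiny_config())
  ev <- tiny_set(3, 41)
  batch <- predict(m, ev)
  singles <- dplyr::bind_rows(lapply(seq_len(nrow(ev)),
                                     function(i) predict(m, ev[i, ])))
  expect_equal(batch, singles, tolerance = 1e-12)
  perm <- sample(nrow(ev))
  expect_equal(predict(m, ev[perm, ]), batch[perm, ], tolerance = 1e-12)
})

test_that("fluorescence masking hits the requested rate and edge cases", {
  ev <- tibble::tibble(event_id = as.character(1:1000),
                       fluorescence = rep(list(rep(1, 13)), 1000))
  expect_identical(mask_fluorescence_batch(ev, 0, 1), ev)
  all_gone <- mask_fluorescence_batch(ev, 1, 1)
  expect_true(all(vapply(all_gone$fluorescence, is.null, logical(1))))
  expect_error(mask_fluorescence_batch(ev, -0.1, 1),
               class = "holopollen_invalid_parameter")
  masked <- mask_fluorescence_batch(ev, 0.3, 7)
  again <- mask_fluorescence_batch(ev, 0.3, 7)
  expect_identical(masked, again)
  # already-absent records stay absent
  pre <- mask_fluorescence_batch(ev, 1, 1)
  expect_true(all(vapply(mask_fluorescence_batch(pre, 0.5, 2)$fluorescence,
                         is.null, logical(1))))
})

test_that("training reaches 100% on a single-class set and is reproducible", {
  ev <- tiny_set(8, 51)
  ev <- ev[ev$true_label == "a", ]
  cfg <- model_config(c("a", "b", "c"), image_side = 16,
                      conv_channels = c(4L), fluor_hidden_units = 4L,
                      epochs = 5L, batch_size = 4L, learning_rate = 0.01,
                      rng_seed = 3L)
  m <- train_model(build_model(cfg), ev)
  expect_identical(nrow(m$report), 5L)
  lab <- apply_confidence_threshold(predict(m, ev), 0)$label
  expect_true(all(lab == "a"))
  m2 <- train_model(build_model(cfg), ev)
  expect_identical(m$params, m2$params)
})

test_that("training rejects unlabelled events and unknown labels", {
  ev <- tiny_set(2, 61)
  bad <- ev; bad$true_label[1] <- NA
  expect_error(train_model(build_model(tiny_config()), bad),
               class = "holopollen_data_error")
  bad2 <- ev; bad2$true_label[1] <- "martian"
  expect_error(train_model(build_model(tiny_config()), bad2),
               class = "holopollen_data_error")
})

test_that("analytic gradients match numerical differentiation", {
  # NB: central differences are only meaningful away from the ReLU kink, so
  # the configuration is chosen with live activations in every layer.
  cfg <- model_config(c("a", "b", "c"), image_side = 8,
                      conv_channels = c(3L), fluor_hidden_units = 4L,
                      rng_seed = 7L)
  m <- build_model(cfg)
  withr::with_seed(1, {
    Ximg <- matrix(runif(2 * 64 * 3), 2 * 64, 3)
    Xfl <- rbind(matrix(runif(13 * 3), 13, 3), 1)
  })
  y <- c(1L, 2L, 3L)
  lg <- holopollen:::nn_loss_grad_cpp(m$params, Ximg, Xfl, y,
                                      cfg$conv_channels, 8L)
  f <- function(p) holopollen:::nn_loss_grad_cpp(p, Ximg, Xfl, y,
                                                 cfg$conv_channels, 8L)$loss
  eps <- 1e-6
  for (nm in names(m$params)) {
    g_num <- lg$grads[[nm]] * 0
    for (i in seq_along(g_num)) {
      up <- m$params; up[[nm]][i] <- up[[nm]][i] + eps
      dn <- m$params; dn[[nm]][i] <- dn[[nm]][i] - eps
      g_num[i] <- (f(up) - f(dn)) / (2 * eps)
    }
    expect_lt(max(abs(g_num - lg$grads[[nm]])), 1e-6)
  }
})

test_that("threshold resolution obeys the >= rule and abstains on ties", {
  pr <- tibble::tibble(event_id = c("e1", "e2", "e3"),
                       probs = list(c(a = 0.9, b = 0.1),
                                    c(a = 0.9, b = 0.1),
                                    c(a = 0.5, b = 0.5)),
                       confidence = c(0.9, 0.9, 0.5))
  expect_identical(apply_confidence_threshold(pr[1, ], 0.5)$label, "a")
  expect_identical(apply_confidence_threshold(pr[2, ], 0.95)$label,
                   "UNCLASSIFIED")
  expect_identical(apply_confidence_threshold(pr[3, ], 0.5)$label,
                   "UNCLASSIFIED")
  expect_identical(apply_confidence_threshold(pr[1, ], 0.9)$label, "a")
  expect_error(apply_confidence_threshold(pr, 1.5),
               class = "holopollen_invalid_parameter")
})

test_that("classified sets are nested as the threshold rises", {
  withr::with_seed(13, {
    n <- 200
    pr <- tibble::tibble(
      event_id = as.character(1:n),
      probs = lapply(1:n, function(i) {
        p <- runif(3); p <- p / sum(p); names(p) <- c("a", "b", "c"); p
      }))
    pr$confidence <- vapply(pr$probs, max, numeric(1))
    grid <- seq(0, 1, by = 0.1)
    sets <- lapply(grid, function(cc) {
      lab <- apply_confidence_threshold(pr, cc)
      lab$event_id[lab$label != "UNCLASSIFIED"]
    })
    for (i in seq_along(grid)[-1])
      expect_true(all(sets[[i]] %in% sets[[i - 1]]))
  })
})

test_that("tidy and glance summarise a fitted model", {
  ev <- tiny_set(6, 71)
  m <- build_model(tiny_config())
  expect_identical(nrow(tidy(m)), 0L)
  m <- train_model(m, ev[1:12, ], ev[13:18, ])
  td <- tidy(m)
  expect_identical(names(td), c("epoch", "loss", "val_accuracy"))
  expect_identical(nrow(td), 5L)
  gl <- glance(m)
  expect_true(gl$trained)
  expect_identical(gl$n_classes, 3L)
  expect_gt(gl$n_parameters, 0)
})
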