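# Shared fixture builders: everything is generated in code at test time.

# Balanced labelled event set from a named profile list.
make_labelled_set <- function(profiles, n_per, seed, side = 32L, scale = 3) {
  seeds <- holopollen:::derive_seeds(seed, n_per * length(profiles))
  i <- 0
  rows <- vector("list", n_per * length(profiles))
  for (p in profiles) {
    for (j in seq_len(n_per)) {
      i <- i + 1
      rows[[i]] <- generate_event(p, as.POSIXct("2024-06-01", tz = "UTC") + i * 60,
                                  "lab", seeds[i], image_side = side,
                                  pixel_scale = scale)
    }
  }
  dplyr::bind_rows(rows)
}

# Minimal event tibble wrapping an arbitrary image (for morphology tests).
image_event <- function(img, pixel_scale = 1, id = "img") {
  tibble::tibble(event_id = id,
                 timestamp = as.POSIXct("2024-06-01", tz = "UTC"),
                 site = "lab",
                 hologram1 = list(img), hologram2 = list(img),
                 fluorescence = list(NULL), true_label = NA_character_,
                 pixel_scale = pixel_scale)
}

# Solid shapes on a noisy background, drawn directly (independent of the
# package's renderer).
shape_image <- function(side, fg, seed = 1) {
  withr::with_seed(seed, {
    img <- matrix(pmax(0, rnorm(side * side, 0.05, 0.01)), side, side)
    img[fg] <- 0.8
    img
  })
}

disc_pixels <- function(side, cx, cy, r) {
  d <- outer(seq_len(side), seq_len(side),
             function(y, x) sqrt((y - cy)^2 + (x - cx)^2))
  d <= r
}

rect_pixels <- function(side, y0, y1, x0, x1) {
  m <- matrix(FALSE, side, side)
  m[y0:y1, x0:x1] <- TRUE
  m
}

# Perfect-information predictions: probability 1 on the true label.
perfect_predictions <- function(events, class_names) {
  tibble::tibble(
    event_id = events$event_id,
    probs = lapply(events$true_label, function(l) {
      p <- setNames(rep(0, length(class_names)), class_names)
      p[l] <- 1
      p
    }),
    confidence = 1)
}

# Daily series helper.
daily_series <- function(values, start = "2024-01-01", site = "s",
                         taxon = "poaceae", source = "manual") {
  concentration_series(site, taxon, "daily",
                       seq(as.POSIXct(start, tz = "UTC"), by = 86400,
                           length.out = length(values)),
                       values, source)
}

# Brute-force out-of-season oracle: enumerate every window explicitly.
off_season_oracle <- function(values, T, W, k) {
  n <- length(values)
  off <- logical(n)
  for (j in seq_len(n - W + 1)) {
    win <- values[j:(j + W - 1)]
    if (sum(win < T) >= k) off[j:(j + W - 1)] <- TRUE
  }
  off
}

# O(n^2) pair-enumeration tau-b oracle.
tau_b_oracle <- function(x, y) {
  n <- length(x)
  C <- 0; D <- 0; tx <- 0; ty <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
    if (dx == 0) tx <- tx + 1
    if (dy == 0) ty <- ty + 1
    if (dx * dy > 0) C <- C + 1
    if (dx * dy < 0) D <- D + 1
  }
  n0 <- n * (n - 1) / 2
  (C - D) / sqrt((n0 - tx) * (n0 - ty))
}
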