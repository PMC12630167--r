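#' Construct a concentration series
#'
#' A concentration series is a tibble of equally spaced daily or hourly
#' particle concentrations (particles per cubic metre) for one site, taxon
#' and source. Daily timestamps are midnights UTC.
#'
#' @param site,taxon Identifiers.
#' @param resolution `"daily"` or `"hourly"`.
#' @param timestamps Strictly increasing, equally spaced UTC instants.
#' @param values Finite, non-negative concentrations (particles/m3).
#' @param source `"manual"`, `"automatic"` or `"true"` (generator truth).
#' @return A tibble with columns `site`, `taxon`, `resolution`, `timestamp`,
#'   `value`, `source`.
#' @export
concentration_series <- function(site, taxon, resolution, timestamps, values,
                                 source) {
  resolution <- match.arg(resolution, c("daily", "hourly"))
  source <- match.arg(source, c("manual", "automatic", "true"))
  timestamps <- as.POSIXct(timestamps, tz = "UTC")
  if (length(timestamps) != length(values))
    stop_invalid("timestamps and values must have equal length")
  if (any(!is.finite(values)) || any(values < 0))
    stop_invalid("concentration values must be finite and >= 0")
  step <- if (resolution == "daily") 86400 else 3600
  if (length(timestamps) > 1) {
    d <- as.numeric(diff(timestamps), units = "secs")
    if (any(abs(d - step) > 1e-6))
      stop_invalid(sprintf(
        "timestamps must be strictly increasing and equally spaced at the %s step",
        resolution))
  }
  tibble::tibble(site = site, taxon = taxon, resolution = resolution,
                 timestamp = timestamps, value = as.numeric(values),
                 source = source)
}

#' Define per-taxon arrival rates and fog episodes
#'
#' The schedule drives the synthetic event stream: piecewise-constant
#' arrival-rate intervals per taxon (events per hour) plus optional fog
#' episodes, which inject water-droplet events only inside their intervals.
#'
#' @param rates Tibble with columns `taxon`, `start`, `end` (UTC instants)
#'   and `rate` (events/hour, >= 0).
#' @param fog_episodes Optional tibble with columns `start`, `end`, `rate`;
#'   each episode adds droplet-class arrivals at `rate` events/hour.
#' @return An `episode_schedule` object.
#' @export
episode_schedule <- function(rates, fog_episodes = NULL) {
  rates <- tibble::as_tibble(rates)
  need <- c("taxon", "start", "end", "rate")
  if (!all(need %in% names(rates)))
    stop_invalid("`rates` needs columns taxon, start, end, rate")
  if (any(rates$rate < 0)) stop_invalid("arrival rates must be >= 0")
  rates$start <- as.POSIXct(rates$start, tz = "UTC")
  rates$end <- as.POSIXct(rates$end, tz = "UTC")
  if (any(rates$end <= rates$start)) stop_invalid("rate intervals need start < end")
  if (!is.null(fog_episodes)) {
    fog_episodes <- tibble::as_tibble(fog_episodes)
    if (!all(c("start", "end", "rate") %in% names(fog_episodes)))
      stop_invalid("`fog_episodes` needs columns start, end, rate")
    if (any(fog_episodes$rate < 0)) stop_invalid("fog rates must be >= 0")
    fog_episodes$start <- as.POSIXct(fog_episodes$start, tz = "UTC")
    fog_episodes$end <- as.POSIXct(fog_episodes$end, tz = "UTC")
    if (any(fog_episodes$end <= fog_episodes$start))
      stop_invalid("fog episodes need start < end")
  }
  structure(list(rates = rates, fog_episodes = fog_episodes),
            class = "episode_schedule")
}

#' Generate a stream of synthetic events from a schedule
#'
#' Per taxon and hour, the number of arrivals is Poisson with mean
#' rate x exposure; fog episodes add droplet-class arrivals only inside
#' their intervals. Every event is rendered with [generate_event()]; all
#' randomness derives from `rng_seed`.
#'
#' @param schedule An [episode_schedule()].
#' @param profiles Named list of [taxon_profile()]s covering every taxon in
#'   the schedule (plus `"droplet"` if fog episodes are present).
#' @param start,end UTC instants bounding the stream (`start < end`).
#' @param site Site identifier.
#' @param rng_seed Integer master seed.
#' @inheritParams render_particle_hologram
#' @return List with `events` (event tibble, timestamp-sorted) and
#'   `manifest` (seed, configuration hash, per-class counts).
#' @export
generate_event_stream <- function(schedule, profiles, start, end, site,
                                  rng_seed, image_side = 200L,
                                  pixel_scale = 0.65) {
  stopifnot(inherits(schedule, "episode_schedule"))
  start <- as.POSIXct(start, tz = "UTC"); end <- as.POSIXct(end, tz = "UTC")
  if (end <= start) stop_invalid("`start` must precede `end`")

  intervals <- schedule$rates
  if (!is.null(schedule$fog_episodes) && nrow(schedule$fog_episodes)) {
    fog <- schedule$fog_episodes
    fog$taxon <- "droplet"
    intervals <- dplyr::bind_rows(intervals, fog[, c("taxon", "start", "end", "rate")])
  }
  for (tx in unique(intervals$taxon))
    if (is.null(profiles[[tx]]))
      stop_invalid(sprintf("no profile supplied for taxon '%s'", tx))

  hours <- seq(trunc(start, "hours"), end - 1e-9, by = "hour")
  draws <- local_seed(rng_seed, {
    out <- list()
    for (i in seq_len(nrow(intervals))) {
      iv <- intervals[i, ]
      for (h in seq_along(hours)) {
        lo <- max(hours[h], iv$start, start)
        hi <- min(hours[h] + 3600, iv$end, end)
        w <- as.numeric(hi - lo, units = "hours")
        if (w <= 0) next
        n <- rpois(1, iv$rate * w)
        if (n > 0) {
          ts <- lo + runif(n, 0, as.numeric(hi - lo, units = "secs"))
          out[[length(out) + 1L]] <- tibble::tibble(taxon = iv$taxon, timestamp = ts)
        }
      }
    }
    if (length(out)) dplyr::bind_rows(out) else
      tibble::tibble(taxon = character(), timestamp = as.POSIXct(character(), tz = "UTC"))
  })
  draws <- dplyr::arrange(draws, .data$timestamp)

  n <- nrow(draws)
  seeds <- derive_seeds(rng_seed + 1L, n)
  h1 <- vector("list", n); h2 <- vector("list", n); fl <- vector("list", n)
  for (i in seq_len(n)) {
    prof <- profiles[[draws$taxon[i]]]
    ss <- derive_seeds(seeds[i], 3L)
    d <- local_seed(ss[1], sample_diameter(prof))
    holos <- render_particle_hologram(prof, d, ss[2], image_side = image_side,
                                      pixel_scale = pixel_scale)
    h1[[i]] <- holos[[1]]; h2[[i]] <- holos[[2]]
    fl[i] <- list(sample_fluorescence(prof, ss[3]))
  }
  events <- if (n) tibble::tibble(
    event_id = sprintf("%s-%s-%06d", site,
                       format(draws$timestamp, "%Y%m%dT%H%M%S", tz = "UTC"),
                       seq_len(n)),
    timestamp = draws$timestamp, site = site,
    hologram1 = h1, hologram2 = h2, fluorescence = fl,
    true_label = draws$taxon, pixel_scale = pixel_scale) else empty_events()

  cfg <- list(rates = schedule$rates, fog = schedule$fog_episodes,
              start = start, end = end, site = site,
              image_side = image_side, pixel_scale = pixel_scale,
              profiles = profiles)
  manifest <- list(seed = as.integer(rng_seed),
                   config_hash = config_hash(cfg),
                   site = site, start = start, end = end,
                   n_events = nrow(events),
                   class_counts = table(events$true_label))
  list(events = events, manifest = manifest)
}

empty_events <- function() {
  tibble::tibble(event_id = character(),
                 timestamp = as.POSIXct(character(), tz = "UTC"),
                 site = character(),
                 hologram1 = list(), hologram2 = list(),
                 fluorescence = list(), true_label = character(),
                 pixel_scale = numeric())
}

#' Emulate a manual (Hirst-type trap) concentration series
#'
#' Draws the manual daily value around `efficiency` x true value with
#' negative-binomial counting noise on an equivalent sampled air volume.
#' `noise_dispersion = 0` is the exact deterministic limit
#' (`manual = efficiency * true`).
#'
#' @param true_daily A daily concentration series (the generator's truth).
#' @param efficiency Multiplicative sampling-efficiency factor (> 0); this is
#'   what the scaling factor S recovers.
#' @param noise_dispersion Negative-binomial dispersion (>= 0); variance of
#'   the daily count is `mu + dispersion * mu^2`.
#' @param rng_seed Integer seed.
#' @param volume_m3 Equivalent daily sampled air volume (m3) converting
#'   concentrations to counts for the noise model.
#' @return A daily concentration series with `source = "manual"`.
#' @export
emulate_manual_series <- function(true_daily, efficiency, noise_dispersion = 0,
                                  rng_seed = 1L, volume_m3 = 14.4) {
  if (!is.numeric(efficiency) || efficiency <= 0)
    stop_invalid("`efficiency` must be > 0")
  if (noise_dispersion < 0) stop_invalid("`noise_dispersion` must be >= 0")
  if (!all(true_daily$resolution == "daily"))
    stop_invalid("`true_daily` must be a daily series")
  mu <- efficiency * true_daily$value
  vals <- if (noise_dispersion == 0) mu else
    local_seed(rng_seed, {
      counts <- rnbinom(length(mu), mu = mu * volume_m3, size = 1 / noise_dispersion)
      counts / volume_m3
    })
  concentration_series(site = true_daily$site[1] %||% "site",
                       taxon = true_daily$taxon[1] %||% "all",
                       resolution = "daily",
                       timestamps = true_daily$timestamp,
                       values = vals, source = "manual")
}
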