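#' Render the synthetic hologram pair for one particle
#'
#' Draws the two greyscale holograms of a single particle as a bright disc of
#' the requested diameter on a dark noisy background. The silhouette carries
#' a multiplicative radial-angular texture of amplitude
#' `profile$texture_amplitude` (zero for water droplets, which appear
#' perfectly smooth) and `profile$spike_count` boundary protrusions. The
#' second hologram is the same particle re-rendered with an independent small
#' jitter of centre, texture phase and background noise, emulating the two
#' reconstruction planes of the instrument. The appearance model is a
#' classifiable proxy for holographic reconstructions, not an optical
#' simulation.
#'
#' @param profile A [taxon_profile()].
#' @param diameter Particle diameter in micrometres (> 0); the disc must fit
#'   inside the frame, i.e. `diameter / pixel_scale < image_side`.
#' @param rng_seed Integer seed; the same seed reproduces the images
#'   bit-for-bit.
#' @param image_side Image side length in pixels (square frames).
#' @param pixel_scale Micrometres per pixel (> 0).
#'
#' @return List of two `image_side` x `image_side` numeric matrices with
#'   intensities in \[0, 1\].
#' @export
render_particle_hologram <- function(profile, diameter, rng_seed,
                                     image_side = 200L, pixel_scale = 0.65) {
  stopifnot(inherits(profile, "taxon_profile"))
  if (!is.numeric(diameter) || length(diameter) != 1L || !is.finite(diameter) ||
      diameter <= 0)
    stop_invalid("`diameter` must be a single positive number")
  if (pixel_scale <= 0) stop_invalid("`pixel_scale` must be > 0")
  image_side <- as.integer(image_side)
  if (diameter / pixel_scale >= image_side)
    stop_invalid(sprintf(
      "particle (%.1f um = %.1f px) does not fit in a %d px frame",
      diameter, diameter / pixel_scale, image_side))

  local_seed(rng_seed, {
    # Texture harmonics shared by the two planes; phases jittered per plane.
    n_harm <- 6L
    amp <- rnorm(n_harm, 0, 1)
    m_ang <- sample(2:7, n_harm, replace = TRUE)
    n_rad <- sample(1:4, n_harm, replace = TRUE)
    ph_a <- runif(n_harm, 0, 2 * pi)
    ph_r <- runif(n_harm, 0, 2 * pi)
    spike_phase <- runif(1, 0, 2 * pi)
    lapply(1:2, function(plane) {
      centre <- (image_side + 1) / 2 + rnorm(2, 0, 0.5)
      jit_a <- ph_a + rnorm(n_harm, 0, 0.2)
      jit_r <- ph_r + rnorm(n_harm, 0, 0.2)
      render_plane(image_side, centre, diameter / (2 * pixel_scale),
                   profile$texture_amplitude, profile$spike_count,
                   spike_phase, amp, m_ang, n_rad, jit_a, jit_r)
    })
  })
}

# One reconstruction plane. Rows index y, columns x; intensities in [0,1].
render_plane <- function(side, centre, radius_px, texture_amplitude,
                         spike_count, spike_phase, amp, m_ang, n_rad,
                         ph_a, ph_r) {
  dx <- matrix(rep(seq_len(side) - centre[2], each = side), side, side)
  dy <- matrix(rep(seq_len(side) - centre[1], times = side), side, side)
  rho <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, dx)

  r_edge <- radius_px
  if (spike_count > 0) {
    bump <- pmax(0, cos(spike_count * theta + spike_phase))^3
    r_edge <- radius_px * (1 + 0.12 * bump)
  }
  # soft silhouette edge (~1 px)
  s <- (r_edge - rho) + 0.5
  s[s < 0] <- 0
  s[s > 1] <- 1

  base <- 0.75
  inside_val <- base
  if (texture_amplitude > 0) {
    tex <- 0
    for (k in seq_along(amp)) {
      tex <- tex + amp[k] *
        cos(m_ang[k] * theta + ph_a[k]) *
        cos(2 * pi * n_rad[k] * rho / radius_px + ph_r[k])
    }
    core <- s > 0.5
    sd_tex <- stats::sd(tex[core])
    if (is.finite(sd_tex) && sd_tex > 0) tex <- tex / sd_tex else tex <- 0
    inside_val <- base * (1 + texture_amplitude * tex)
  }
  bg <- pmax(0, matrix(rnorm(side * side, 0.08, 0.02), side, side))
  img <- bg * (1 - s) + s * inside_val
  img[img < 0] <- 0
  img[img > 1] <- 1
  img
}

#' Sample a 13-channel induced-fluorescence vector
#'
#' With probability `profile$fluor_missing_prob` the event carries no
#' fluorescence record (returns `NULL`); otherwise each of the 13 channels is
#' drawn as `max(0, Normal(mean, sd))`.
#'
#' @inheritParams render_particle_hologram
#' @return Numeric vector of length 13 (all >= 0), or `NULL` when the
#'   modality is absent.
#' @export
sample_fluorescence <- function(profile, rng_seed) {
  stopifnot(inherits(profile, "taxon_profile"))
  local_seed(rng_seed, {
    if (runif(1) < profile$fluor_missing_prob) return(NULL)
    pmax(0, rnorm(13, profile$fluor_means, profile$fluor_sds))
  })
}

# Truncated-normal diameter draw on the profile's support.
sample_diameter <- function(profile) {
  lo <- profile$diameter_range[1]; hi <- profile$diameter_range[2]
  for (i in 1:100) {
    d <- rnorm(1, profile$diameter_mean, profile$diameter_sd)
    if (d >= lo && d <= hi) return(d)
  }
  min(hi, max(lo, profile$diameter_mean))
}

#' Generate one synthetic event record
#'
#' Composes the hologram renderer and the fluorescence sampler into a full
#' event: two greyscale holograms, an optional 13-channel fluorescence
#' vector, a timestamp, a site and the generating class as `true_label`.
#'
#' @inheritParams render_particle_hologram
#' @param timestamp A UTC `POSIXct` instant.
#' @param site Site identifier.
#' @return One-row event tibble (see [validate_events()] for the schema).
#' @export
generate_event <- function(profile, timestamp, site, rng_seed,
                           image_side = 200L, pixel_scale = 0.65) {
  stopifnot(inherits(profile, "taxon_profile"))
  timestamp <- as.POSIXct(timestamp, tz = "UTC")
  seeds <- derive_seeds(rng_seed, 3L)
  d <- local_seed(seeds[1], sample_diameter(profile))
  holos <- render_particle_hologram(profile, d, seeds[2],
                                    image_side = image_side,
                                    pixel_scale = pixel_scale)
  fl <- sample_fluorescence(profile, seeds[3])
  tibble::tibble(
    event_id = sprintf("%s-%s-%08x", site,
                       format(timestamp, "%Y%m%dT%H%M%S", tz = "UTC"),
                       as.integer(rng_seed) %% 0xFFFFFFF),
    timestamp = timestamp,
    site = site,
    hologram1 = list(holos[[1]]),
    hologram2 = list(holos[[2]]),
    fluorescence = list(fl),
    true_label = profile$name,
    pixel_scale = pixel_scale)
}

#' Validate an event table against the data-model invariants
#'
#' Checks that every record carries exactly two identically sized square
#' greyscale holograms with intensities in \[0, 1\], that fluorescence, when
#' present, has exactly 13 non-negative entries, that timestamps are UTC and
#' pixel scales positive.
#'
#' @param events Event tibble with columns `event_id`, `timestamp`, `site`,
#'   `hologram1`, `hologram2`, `fluorescence`, `true_label`, `pixel_scale`.
#' @return `events`, invisibly, if valid; otherwise an error.
#' @export
validate_events <- function(events) {
  need <- c("event_id", "timestamp", "site", "hologram1", "hologram2",
            "fluorescence", "true_label", "pixel_scale")
  miss <- setdiff(need, names(events))
  if (length(miss))
    stop_data(paste("missing event columns:", paste(miss, collapse = ", ")))
  if (anyDuplicated(events$event_id))
    stop_data("event_id values must be unique")
  if (!inherits(events$timestamp, "POSIXct") ||
      !identical(attr(events$timestamp, "tzone"), "UTC"))
    stop_data("timestamps must be POSIXct in UTC")
  if (any(events$pixel_scale <= 0)) stop_data("pixel_scale must be > 0")
  for (i in seq_len(nrow(events))) {
    h1 <- events$hologram1[[i]]; h2 <- events$hologram2[[i]]
    if (!is.matrix(h1) || !is.matrix(h2) || !all(dim(h1) == dim(h2)) ||
        nrow(h1) != ncol(h1))
      stop_data(sprintf("event %s: holograms must be two identically sized square matrices",
                        events$event_id[i]))
    if (min(h1, h2) < 0 || max(h1, h2) > 1)
      stop_data(sprintf("event %s: hologram intensities outside [0,1]",
                        events$event_id[i]))
    fl <- events$fluorescence[[i]]
    if (!is.null(fl) && (length(fl) != 13L || any(fl < 0)))
      stop_data(sprintf("event %s: fluorescence must have 13 entries >= 0",
                        events$event_id[i]))
  }
  invisible(events)
}
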