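#' Generative parameters for one particle class
#'
#' A taxon profile holds everything the synthetic generator needs to draw
#' events of one particle class: a diameter distribution (micrometres), the
#' morphological texture of the silhouette, the number of boundary
#' protrusions, and the 13-channel induced-fluorescence response. Water
#' droplets are represented as a perfectly smooth, non-fluorescent class with
#' diameters supported on 10--100 um.
#'
#' @param name Class name (e.g. `"poaceae"`, `"droplet"`).
#' @param diameter_mean,diameter_sd Diameter distribution in micrometres;
#'   draws are truncated to `diameter_range`.
#' @param diameter_range Hard support of the diameter distribution (um).
#' @param texture_amplitude Dimensionless multiplicative texture amplitude
#'   inside the silhouette; 0 means perfectly smooth (a droplet).
#' @param spike_count Integer number of boundary protrusions (>= 0).
#' @param fluor_means,fluor_sds Length-13 non-negative vectors: per-channel
#'   mean intensity and spread of the induced-fluorescence response.
#' @param fluor_missing_prob Probability in \[0,1\] that an event of this
#'   class carries no fluorescence signal at all (module absent or signal
#'   below the noise floor).
#'
#' @return An object of class `taxon_profile` (a named list).
#' @export
taxon_profile <- function(name,
                          diameter_mean, diameter_sd,
                          texture_amplitude = 0,
                          spike_count = 0L,
                          fluor_means = rep(0, 13),
                          fluor_sds = rep(0, 13),
                          fluor_missing_prob = 0,
                          diameter_range = c(1, Inf)) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop_invalid("`name` must be a single non-empty string")
  if (!is.numeric(diameter_mean) || diameter_mean <= 0)
    stop_invalid("`diameter_mean` must be > 0")
  if (diameter_sd < 0) stop_invalid("`diameter_sd` must be >= 0")
  if (texture_amplitude < 0) stop_invalid("`texture_amplitude` must be >= 0")
  spike_count <- as.integer(spike_count)
  if (spike_count < 0) stop_invalid("`spike_count` must be >= 0")
  if (length(fluor_means) != 13L || any(fluor_means < 0))
    stop_invalid("`fluor_means` must be 13 non-negative values")
  if (length(fluor_sds) != 13L || any(fluor_sds < 0))
    stop_invalid("`fluor_sds` must be 13 non-negative values")
  if (fluor_missing_prob < 0 || fluor_missing_prob > 1)
    stop_invalid("`fluor_missing_prob` must be in [0,1]")
  if (length(diameter_range) != 2L || diameter_range[1] <= 0 ||
      diameter_range[1] >= diameter_range[2])
    stop_invalid("`diameter_range` must be an increasing positive pair")
  structure(
    list(name = name,
         diameter_mean = as.numeric(diameter_mean),
         diameter_sd = as.numeric(diameter_sd),
         diameter_range = as.numeric(diameter_range),
         texture_amplitude = as.numeric(texture_amplitude),
         spike_count = spike_count,
         fluor_means = as.numeric(fluor_means),
         fluor_sds = as.numeric(fluor_sds),
         fluor_missing_prob = as.numeric(fluor_missing_prob)),
    class = "taxon_profile")
}

#' @export
print.taxon_profile <- function(x, ...) {
  cat(sprintf("<taxon_profile> %s: d = %.1f +/- %.1f um, texture %.2f, %d spikes, P(no fluor) = %.2f\n",
              x$name, x$diameter_mean, x$diameter_sd, x$texture_amplitude,
              x$spike_count, x$fluor_missing_prob))
  invisible(x)
}

# Smooth unimodal spectral response peaking at `peak` (channel index 1..13).
# Amplitude ~1 at the peak; width ~1.6 channels. A second harmonic peak can
# be added to emulate dual excitation/emission bands.
fluor_bump <- function(peak, amplitude = 1, width = 1.6, peak2 = NULL,
                       amplitude2 = 0.6) {
  ch <- 1:13
  v <- amplitude * exp(-((ch - peak)^2) / (2 * width^2))
  if (!is.null(peak2))
    v <- v + amplitude2 * exp(-((ch - peak2)^2) / (2 * width^2))
  v
}

#' Default particle-class profiles
#'
#' Profiles for the main allergenic pollen taxa monitored in Switzerland
#' (grasses, birch, hazel, alder, ash, oak, beech) plus water droplets.
#' Diameters follow typical grain sizes; the three Betulaceae (birch family)
#' classes are deliberately constructed with identical morphology (same
#' diameter and texture ranges) but well-separated fluorescence channel
#' means, mirroring the fact that they are hard to distinguish by holography
#' alone while their fluorescence responses differ. Droplets are smooth,
#' non-fluorescent, and supported on 10--100 um.
#'
#' @return Named list of [taxon_profile()] objects.
#' @export
default_profiles <- function() {
  sds <- rep(0.12, 13)
  betu_morph <- list(diameter_mean = 24, diameter_sd = 3,
                     texture_amplitude = 0.3, spike_count = 3L)
  lst <- list(
    poaceae = taxon_profile("poaceae", 32, 4,
                            texture_amplitude = 0.12, spike_count = 0L,
                            fluor_means = fluor_bump(3),
                            fluor_sds = sds, fluor_missing_prob = 0.1),
    betula = taxon_profile("betula", betu_morph$diameter_mean, betu_morph$diameter_sd,
                           texture_amplitude = betu_morph$texture_amplitude,
                           spike_count = betu_morph$spike_count,
                           fluor_means = fluor_bump(6),
                           fluor_sds = sds, fluor_missing_prob = 0.1),
    alnus = taxon_profile("alnus", betu_morph$diameter_mean, betu_morph$diameter_sd,
                          texture_amplitude = betu_morph$texture_amplitude,
                          spike_count = betu_morph$spike_count,
                          fluor_means = fluor_bump(9),
                          fluor_sds = sds, fluor_missing_prob = 0.1),
    corylus = taxon_profile("corylus", betu_morph$diameter_mean, betu_morph$diameter_sd,
                            texture_amplitude = betu_morph$texture_amplitude,
                            spike_count = betu_morph$spike_count,
                            fluor_means = fluor_bump(12),
                            fluor_sds = sds, fluor_missing_prob = 0.1),
    fraxinus = taxon_profile("fraxinus", 22, 3,
                             texture_amplitude = 0.45, spike_count = 6L,
                             fluor_means = fluor_bump(2, peak2 = 8),
                             fluor_sds = sds, fluor_missing_prob = 0.1),
    quercus = taxon_profile("quercus", 30, 4,
                            texture_amplitude = 0.5, spike_count = 8L,
                            fluor_means = fluor_bump(5, peak2 = 11),
                            fluor_sds = sds, fluor_missing_prob = 0.1),
    fagus = taxon_profile("fagus", 42, 5,
                          texture_amplitude = 0.35, spike_count = 12L,
                          fluor_means = fluor_bump(7, amplitude = 1.2),
                          fluor_sds = sds, fluor_missing_prob = 0.1),
    droplet = droplet_profile()
  )
  lst
}

#' Water-droplet profile
#'
#' Perfectly smooth (zero texture, no boundary protrusions), non-fluorescent,
#' with diameters on 10--100 um, the size range in which droplets occur under
#' saturated atmospheric conditions and get confused with smooth round pollen
#' grains.
#'
#' @param diameter_mean,diameter_sd Diameter distribution (um), truncated to
#'   10--100 um.
#' @param fluor_missing_prob Probability the event carries no fluorescence
#'   record at all.
#' @export
droplet_profile <- function(diameter_mean = 40, diameter_sd = 15,
                            fluor_missing_prob = 0.2) {
  taxon_profile("droplet", diameter_mean, diameter_sd,
                texture_amplitude = 0, spike_count = 0L,
                fluor_means = rep(0, 13), fluor_sds = rep(0.02, 13),
                fluor_missing_prob = fluor_missing_prob,
                diameter_range = c(10, 100))
}

#' Fog-confusion scenario profiles
#'
#' Emulates the operational failure mode in which grass-pollen-sized water
#' droplets appearing under fog are confused with smooth round grass grains:
#' the droplet class is restricted to grass-like diameters (still within the
#' 10--100 um droplet range), the grass class is given a very low texture
#' amplitude, and a morphologically distinct birch class is included as a
#' third category. Holography alone is close to uninformative for the
#' grass/droplet pair, while induced fluorescence separates them cleanly
#' (pollen fluoresces, droplets do not).
#'
#' @return Named list of three [taxon_profile()] objects
#'   (`poaceae`, `droplet`, `betula`).
#' @export
fog_confusion_profiles <- function() {
  base <- default_profiles()
  list(
    poaceae = taxon_profile("poaceae", 32, 4,
                            texture_amplitude = 0.06, spike_count = 0L,
                            fluor_means = fluor_bump(3),
                            fluor_sds = rep(0.12, 13), fluor_missing_prob = 0.05),
    droplet = taxon_profile("droplet", 32, 5,
                            texture_amplitude = 0, spike_count = 0L,
                            fluor_means = rep(0, 13), fluor_sds = rep(0.02, 13),
                            fluor_missing_prob = 0.1,
                            diameter_range = c(10, 100)),
    betula = base$betula
  )
}
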