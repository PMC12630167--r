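#' Morphological descriptors of an event silhouette
#'
#' Deterministic shape measurements feeding the prefilter that removes
#' non-biological particles before classification. The first hologram is
#' thresholded (Otsu), the largest connected component (holes filled) is the
#' silhouette, and the descriptors are its equivalent diameter
#' (`pixel_scale * 2 * sqrt(area / pi)`, micrometres), solidity (area over
#' convex-hull area) and moment eccentricity.
#'
#' @param events Event tibble.
#' @param min_area Components smaller than this many pixels count as an empty
#'   frame (background noise speckle).
#' @return Tibble with one row per event: `event_id`, `found` (FALSE is the
#'   empty-frame sentinel), `equivalent_diameter`, `solidity`,
#'   `eccentricity`.
#' @export
morphological_descriptors <- function(events, min_area = 10L) {
  purrr::map_dfr(seq_len(nrow(events)), function(i) {
    d <- silhouette_descriptors(events$hologram1[[i]], events$pixel_scale[i],
                                min_area)
    tibble::tibble(event_id = events$event_id[i], found = d$found,
                   equivalent_diameter = d$equivalent_diameter,
                   solidity = d$solidity, eccentricity = d$eccentricity)
  })
}

silhouette_descriptors <- function(img, pixel_scale, min_area = 10L) {
  empty <- list(found = FALSE, equivalent_diameter = NA_real_,
                solidity = NA_real_, eccentricity = NA_real_)
  if (max(img) - min(img) < 1e-6) return(empty)
  thr <- EBImage::otsu(img, range = c(0, 1))
  mask <- EBImage::fillHull(img > thr)
  lab <- EBImage::bwlabel(mask)
  if (max(lab) == 0) return(empty)
  areas <- tabulate(lab[lab > 0])
  big <- which.max(areas)
  if (areas[big] < min_area) return(empty)
  idx <- which(lab == big, arr.ind = TRUE)
  area <- nrow(idx)

  # moment eccentricity from the pixel-coordinate covariance
  cc <- sweep(idx, 2, colMeans(idx))
  cv <- crossprod(cc) / area
  ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ecc <- if (ev[1] <= 0) 0 else sqrt(max(0, 1 - ev[2] / ev[1]))

  # solidity from the convex hull of the component pixels (shoelace area,
  # padded by the half-pixel footprint so a digitised disc scores ~1)
  hull <- idx[grDevices::chull(idx), , drop = FALSE]
  hull_area <- polygon_area(hull) + area_perimeter_pad(idx)
  sol <- min(1, area / max(hull_area, area))

  list(found = TRUE,
       equivalent_diameter = pixel_scale * 2 * sqrt(area / pi),
       solidity = sol, eccentricity = ecc)
}

polygon_area <- function(p) {
  if (nrow(p) < 3) return(nrow(p))
  x <- p[, 1]; y <- p[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# Pixel-centre hulls underestimate the digitised footprint by roughly half a
# pixel along the boundary; approximate the deficit from the hull perimeter.
area_perimeter_pad <- function(idx) {
  hull <- idx[grDevices::chull(idx), , drop = FALSE]
  per <- sum(sqrt(rowSums((hull - hull[c(2:nrow(hull), 1), , drop = FALSE])^2)))
  per / 2 + 1
}

#' Deterministic morphological prefilter
#'
#' Accepts an event iff its silhouette diameter lies in
#' `[d_min, d_max]` micrometres, its solidity is at least `s_min` and its
#' eccentricity at most `e_max`. Empty frames and out-of-bounds shapes are
#' rejected with a reason code; the decision involves no randomness.
#'
#' @param events Event tibble.
#' @param d_min,d_max Diameter bounds (um).
#' @param s_min Minimum solidity.
#' @param e_max Maximum eccentricity.
#' @return Tibble `event_id`, `accept`, `reason`
#'   (`NA`, `"empty"`, `"size"`, `"solidity"` or `"eccentricity"`), plus the
#'   descriptor columns.
#' @export
prefilter_event <- function(events, d_min = 5, d_max = 150,
                            s_min = 0.8, e_max = 0.95) {
  d <- morphological_descriptors(events)
  d$reason <- dplyr::case_when(
    !d$found ~ "empty",
    d$equivalent_diameter < d_min | d$equivalent_diameter > d_max ~ "size",
    d$solidity < s_min ~ "solidity",
    d$eccentricity > e_max ~ "eccentricity",
    TRUE ~ NA_character_)
  d$accept <- is.na(d$reason)
  d[, c("event_id", "accept", "reason", "found", "equivalent_diameter",
        "solidity", "eccentricity")]
}
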