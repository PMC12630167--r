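#' Evaluate the three monitoring metrics at one confidence threshold
#'
#' Applies the threshold, aggregates the retained labels of the target taxon
#' into a daily automatic concentration series over the manual series' span,
#' derives the out-of-season mask from the manual series, and computes
#' Kendall's tau-b, the scaling factor and the off-season noise ratio.
#'
#' @param predictions Prediction tibble from [predict.pollen_model()].
#' @param events Event tibble the predictions refer to (for timestamps).
#' @param manual_daily Daily manual concentration series spanning the event
#'   period.
#' @param c Confidence threshold in \[0,1\].
#' @param taxon Taxon the metrics refer to.
#' @param sample_flow Instrument flow (m3/h) for the count-to-concentration
#'   conversion.
#' @param T,W,k Out-of-season rule parameters (see [detect_off_season()]).
#' @return One-row tibble: `threshold`, `tau`, `scaling`, `noise_ratio`,
#'   `counts_retained` (undefined metrics are `NA` sentinels).
#' @export
evaluate_at_threshold <- function(predictions, events, manual_daily, c, taxon,
                                  sample_flow = 2.4, T = 20, W = 7L, k = 4L) {
  labelled <- apply_confidence_threshold(predictions, c)
  labelled <- dplyr::inner_join(
    labelled, events[, c("event_id", "timestamp")], by = "event_id")
  if (nrow(labelled) != nrow(predictions))
    stop_invalid("predictions do not cover the event table",
                 class = "holopollen_input_error")
  span <- range(manual_daily$timestamp)
  counts <- aggregate_counts(labelled, "daily", taxon,
                             start = span[1], end = span[2] + 86400)
  auto <- counts_to_concentration(counts, sample_flow, "daily",
                                  site = manual_daily$site[1], taxon = taxon)
  mask <- detect_off_season(manual_daily, T = T, W = W, k = k)
  m <- match(auto$timestamp, manual_daily$timestamp)
  tibble::tibble(
    threshold = c,
    tau = kendall_tau_b(manual_daily$value[m], auto$value),
    scaling = scaling_factor(manual_daily, auto),
    noise_ratio = off_season_noise_ratio(auto, mask),
    counts_retained = sum(labelled$label == taxon))
}

#' Sweep the metrics over confidence thresholds
#'
#' Computes the three metrics at each threshold of an ascending grid,
#' mirroring the threshold-dependence analysis used to choose an operational
#' confidence threshold. Undefined metrics are recorded as `NA` sentinels,
#' never dropped.
#'
#' @inheritParams evaluate_at_threshold
#' @param thresholds Ascending confidence thresholds in \[0,1\].
#' @param site Site identifier attached to the curve.
#' @return A `metric_curve` tibble: `site`, `taxon`, `threshold`, `tau`,
#'   `scaling`, `noise_ratio`, `counts_retained`.
#' @export
threshold_sweep <- function(predictions, events, manual_daily, thresholds,
                            taxon, sample_flow = 2.4, T = 20, W = 7L,
                            k = 4L, site = manual_daily$site[1]) {
  if (is.unsorted(thresholds, strictly = FALSE) ||
      any(thresholds < 0 | thresholds > 1))
    stop_invalid("`thresholds` must be ascending values in [0,1]")
  out <- purrr::map_dfr(thresholds, function(cc)
    evaluate_at_threshold(predictions, events, manual_daily, cc, taxon,
                          sample_flow = sample_flow, T = T, W = W, k = k))
  out <- tibble::add_column(out, site = site, taxon = taxon, .before = 1)
  class(out) <- c("metric_curve", class(out))
  out
}

#' Cross-site envelope of metric curves
#'
#' Pointwise mean, minimum and maximum of each metric across sites sharing a
#' threshold grid, with the number of sites contributing at each point
#' (undefined `NA` sentinels are excluded from the statistics but counted).
#'
#' @param curves List of `metric_curve` tibbles on identical threshold
#'   grids.
#' @return A `site_envelope` tibble: `taxon`, `threshold`, `metric`, `mean`,
#'   `min`, `max`, `n_sites`.
#' @export
cross_site_envelope <- function(curves) {
  if (!length(curves)) stop_invalid("no curves supplied",
                                    class = "holopollen_input_error")
  grid <- curves[[1]]$threshold
  for (cu in curves)
    if (!isTRUE(all.equal(cu$threshold, grid)))
      stop_invalid("curves have mismatched threshold grids",
                   class = "holopollen_input_error")
  all <- dplyr::bind_rows(lapply(curves, as.data.frame))
  long <- tidyr::pivot_longer(
    all, cols = c("tau", "scaling", "noise_ratio"),
    names_to = "metric", values_to = "value")
  out <- long |>
    dplyr::group_by(.data$taxon, .data$threshold, .data$metric) |>
    dplyr::summarise(
      mean = if (any(!is.na(.data$value))) mean(.data$value, na.rm = TRUE) else NA_real_,
      min = if (any(!is.na(.data$value))) min(.data$value, na.rm = TRUE) else NA_real_,
      max = if (any(!is.na(.data$value))) max(.data$value, na.rm = TRUE) else NA_real_,
      n_sites = sum(!is.na(.data$value)), .groups = "drop")
  class(out) <- c("site_envelope", class(out))
  out
}
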