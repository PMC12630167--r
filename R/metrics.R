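#' Aggregate labelled events into per-bin counts
#'
#' Counts events of one taxon per UTC calendar bin (hour or day) over a
#' stated span; bins without events are zero, and the counts sum to the
#' number of matching labelled events.
#'
#' @param labelled_events Tibble with at least `timestamp` and `label`
#'   columns (threshold-resolved labels; `"UNCLASSIFIED"` is excluded).
#' @param resolution `"hourly"` or `"daily"`.
#' @param taxon Class to count.
#' @param start,end Span of the output series (defaults to the event range);
#'   bins are `[start, end)`.
#' @return Tibble with `timestamp` (bin start, UTC) and `count`.
#' @export
aggregate_counts <- function(labelled_events, resolution, taxon,
                             start = NULL, end = NULL) {
  resolution <- match.arg(resolution, c("hourly", "daily"))
  if (!"label" %in% names(labelled_events))
    stop_data("events must carry a threshold-resolved `label` column")
  if (anyNA(labelled_events$label))
    stop_data("unresolved (NA) labels present")
  unit <- if (resolution == "hourly") "hours" else "days"
  step <- if (resolution == "hourly") 3600 else 86400
  ts <- labelled_events$timestamp
  start <- trunc(as.POSIXct(start %||% min(ts), tz = "UTC"), unit)
  end <- as.POSIXct(end %||% (max(ts) + 1), tz = "UTC")
  bins <- seq(start, end, by = step)
  bins <- bins[as.numeric(bins) < as.numeric(end)]
  keep <- labelled_events$label == taxon &
    labelled_events$timestamp >= start & labelled_events$timestamp < end
  binned <- trunc(labelled_events$timestamp[keep], unit)
  counts <- table(factor(format(binned, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
                         levels = format(bins, "%Y-%m-%d %H:%M:%S", tz = "UTC")))
  tibble::tibble(timestamp = bins, count = as.integer(counts))
}

#' Convert counts to concentrations
#'
#' Divides per-bin counts by the sampled air volume
#' (`sample_flow` x bin duration) to obtain particles per cubic metre;
#' `source` is set to `"automatic"`.
#'
#' @param counts Tibble from [aggregate_counts()].
#' @param sample_flow Instrument sample flow in m3/hour (> 0).
#' @param resolution `"hourly"` or `"daily"`.
#' @param site,taxon Identifiers carried into the series.
#' @param source Series source tag.
#' @return A concentration series (see [concentration_series()]).
#' @export
counts_to_concentration <- function(counts, sample_flow, resolution,
                                    site = "site", taxon = "all",
                                    source = "automatic") {
  if (!is.numeric(sample_flow) || sample_flow <= 0)
    stop_invalid("`sample_flow` must be > 0")
  resolution <- match.arg(resolution, c("hourly", "daily"))
  hours <- if (resolution == "hourly") 1 else 24
  concentration_series(site, taxon, resolution, counts$timestamp,
                       counts$count / (sample_flow * hours), source)
}

#' Data-driven out-of-season mask
#'
#' A day is out of season iff it belongs to at least one sliding window of
#' `W` consecutive days in which at least `k` days have an average daily
#' concentration below `T` particles/m3, based on the manual measurements.
#' Windows never cross the series boundaries. Defaults: `T = 20`, `W = 7`,
#' `k = 4`.
#'
#' @param manual_daily Daily manual concentration series (length >= `W`).
#' @param T Concentration threshold (particles/m3).
#' @param W Window length in days.
#' @param k Minimum number of sub-threshold days per qualifying window
#'   (`k <= W`).
#' @return A `season_mask` tibble: `timestamp`, `off_season` (logical), with
#'   the parameters and the reference series identity as attributes.
#' @export
detect_off_season <- function(manual_daily, T = 20, W = 7L, k = 4L) {
  if (!all(manual_daily$resolution == "daily"))
    stop_invalid("season detection requires a daily series",
                 class = "holopollen_input_error")
  if (!all(manual_daily$source == "manual"))
    stop_invalid("season detection is defined on the manual series",
                 class = "holopollen_input_error")
  n <- nrow(manual_daily)
  W <- as.integer(W); k <- as.integer(k)
  if (T <= 0 || W <= 0 || k <= 0 || k > W)
    stop_invalid("need T > 0, W > 0, 0 < k <= W")
  if (n < W)
    stop_invalid(sprintf("series length %d shorter than window W = %d", n, W),
                 class = "holopollen_input_error")
  low <- manual_daily$value < T
  # windows start at 1..n-W+1; window j qualifies iff >= k low days
  csum <- cumsum(c(0L, low))
  win_low <- csum[(W + 1):(n + 1)] - csum[1:(n - W + 1)]
  qual <- win_low >= k
  off <- logical(n)
  for (j in which(qual)) off[j:(j + W - 1L)] <- TRUE
  out <- tibble::tibble(timestamp = manual_daily$timestamp, off_season = off)
  attr(out, "params") <- list(T = T, W = W, k = k)
  attr(out, "reference") <- paste(manual_daily$site[1], manual_daily$taxon[1],
                                  sep = "/")
  class(out) <- c("season_mask", class(out))
  out
}

#' Kendall's tau-b rank correlation
#'
#' Tie-corrected Kendall correlation,
#' `(C - D) / sqrt((n0 - t_x) (n0 - t_y))` over all pairs, where `C`/`D`
#' count concordant/discordant pairs, `n0 = n(n-1)/2` and `t_x`, `t_y` the
#' within-tie pair counts. Chosen over the Pearson coefficient for its
#' robustness to outliers; ties at zero dominate pollen series, hence the
#' tau-b correction. Returns the undefined-metric sentinel `NA` when either
#' vector is constant.
#'
#' @param x,y Paired numeric vectors of equal length >= 2.
#' @return tau in \[-1, 1\], or `NA` if undefined.
#' @export
kendall_tau_b <- function(x, y) {
  if (length(x) != length(y))
    stop_invalid("`x` and `y` must have equal length",
                 class = "holopollen_input_error")
  n <- length(x)
  if (n < 2) stop_invalid("need at least two paired observations",
                          class = "holopollen_input_error")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) return(NA_real_)
  sx <- sign(outer(x, x, "-")); sy <- sign(outer(y, y, "-"))
  up <- upper.tri(sx)
  s <- sx[up] * sy[up]
  C <- sum(s > 0); D <- sum(s < 0)
  n0 <- n * (n - 1) / 2
  tie_pairs <- function(v) {
    t <- table(v); sum(t * (t - 1) / 2)
  }
  (C - D) / sqrt((n0 - tie_pairs(x)) * (n0 - tie_pairs(y)))
}

#' Scaling factor between manual and automatic series
#'
#' `S` is the ratio of the manual total to the automatic total over the
#' common period; the lower the scaling factor, the better the sampling by
#' the automatic system. Returns the undefined-metric sentinel `NA` (not
#' infinity) when the automatic total is zero.
#'
#' @param manual,automatic Concentration series at the same resolution.
#' @return `S > 0`, or `NA` if undefined.
#' @export
scaling_factor <- function(manual, automatic) {
  common <- intersect(manual$timestamp, automatic$timestamp)
  if (!length(common))
    stop_invalid("no overlapping period between the series",
                 class = "holopollen_input_error")
  m <- sum(manual$value[manual$timestamp %in% common])
  a <- sum(automatic$value[automatic$timestamp %in% common])
  if (a == 0) return(NA_real_)
  m / a
}

#' Off-season noise ratio
#'
#' The mean automatic daily concentration over out-of-season days divided by
#' the mean over in-season days: an indicator of classifier false-positive
#' noise (lower means fewer incorrect warnings outside the pollen season).
#' Returns the undefined-metric sentinel `NA` when there are no off-season
#' days or the in-season mean is zero.
#'
#' @param automatic_daily Daily automatic concentration series.
#' @param mask A `season_mask` from [detect_off_season()] covering the
#'   series.
#' @return `R >= 0`, or `NA` if undefined.
#' @export
off_season_noise_ratio <- function(automatic_daily, mask) {
  m <- match(automatic_daily$timestamp, mask$timestamp)
  if (anyNA(m))
    stop_invalid("season mask does not cover the automatic series",
                 class = "holopollen_input_error")
  off <- mask$off_season[m]
  if (!any(off) || !any(!off)) return(NA_real_)
  denom <- mean(automatic_daily$value[!off])
  if (denom == 0) return(NA_real_)
  mean(automatic_daily$value[off]) / denom
}
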