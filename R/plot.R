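#' Plot a metric curve
#'
#' Kendall's tau, the scaling factor and the off-season noise ratio as
#' functions of the confidence threshold, one panel per metric.
#'
#' @param object A `metric_curve` from [threshold_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.metric_curve <- function(object, ...) {
  long <- tidyr::pivot_longer(as.data.frame(object),
                              cols = c("tau", "scaling", "noise_ratio"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$threshold, .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::scale_colour_manual(values = c(tau = "#d62728",
                                            scaling = "#2ca02c",
                                            noise_ratio = "#ff7f0e"),
                                 guide = "none") +
    ggplot2::labs(x = "confidence threshold",
                  y = NULL,
                  title = sprintf("%s @ %s", object$taxon[1], object$site[1]))
}

#' Plot a cross-site envelope
#'
#' Mean metric lines with min/max shading across sites, one panel per
#' metric.
#'
#' @param object A `site_envelope` from [cross_site_envelope()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.site_envelope <- function(object, ...) {
  ggplot2::ggplot(as.data.frame(object),
                  ggplot2::aes(.data$threshold, .data$mean,
                               colour = .data$metric, fill = .data$metric)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$min, ymax = .data$max),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::scale_colour_manual(values = c(tau = "#d62728",
                                            scaling = "#2ca02c",
                                            noise_ratio = "#ff7f0e"),
                                 aesthetics = c("colour", "fill"),
                                 guide = "none") +
    ggplot2::labs(x = "confidence threshold", y = NULL,
                  title = sprintf("%s: cross-site envelope", object$taxon[1]))
}

#' Display one event's hologram pair
#'
#' @param events Event tibble.
#' @param i Row index.
#' @return A ggplot object with the two greyscale holograms side by side.
#' @export
plot_hologram <- function(events, i = 1L) {
  df <- purrr::map_dfr(1:2, function(plane) {
    m <- events[[paste0("hologram", plane)]][[i]]
    tibble::tibble(plane = paste("plane", plane),
                   y = rep(seq_len(nrow(m)), ncol(m)),
                   x = rep(seq_len(ncol(m)), each = nrow(m)),
                   value = as.vector(m))
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~plane) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1), guide = "none") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = events$event_id[i], x = NULL, y = NULL)
}
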