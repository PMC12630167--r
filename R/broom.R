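#' Tidy the per-epoch training report of a model
#'
#' @param x A `pollen_model`.
#' @param ... Unused.
#' @return Tibble with `epoch`, `loss` and `val_accuracy` (empty for an
#'   untrained model).
#' @export
tidy.pollen_model <- function(x, ...) {
  if (is.null(x$report))
    return(tibble::tibble(epoch = integer(), loss = numeric(),
                          val_accuracy = numeric()))
  tibble::as_tibble(x$report)
}

#' One-row summary of a model
#'
#' @param x A `pollen_model`.
#' @param ... Unused.
#' @return Tibble with class count, parameter count, training status, final
#'   loss and held-out accuracy, seed and configuration hash.
#' @export
glance.pollen_model <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, numeric(1)))
  rep <- x$report
  tibble::tibble(
    n_classes = length(x$class_names),
    n_parameters = n_par,
    image_side = x$config$image_side,
    trained = x$trained,
    epochs = if (is.null(rep)) 0L else nrow(rep),
    final_loss = if (is.null(rep)) NA_real_ else rep$loss[nrow(rep)],
    val_accuracy = if (is.null(rep)) NA_real_ else rep$val_accuracy[nrow(rep)],
    seed = x$config$rng_seed,
    config_hash = config_hash(unclass(x$config)))
}
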