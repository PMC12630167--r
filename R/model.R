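#' Configuration of the two-branch classifier
#'
#' The image branch is a compact VGG-style convolutional network over the two
#' stacked holograms: each block applies two 3x3 convolutions (ReLU) followed
#' by 2x2 max-pooling, with `conv_channels[k]` feature maps in block `k`. The
#' fluorescence branch is a single small dense layer (`fluor_hidden_units`
#' units, kept deliberately few to avoid over-complex fluorescence features)
#' over the 13 channels plus a presence flag. The branches are fused by
#' concatenation into a linear softmax head. During training a fraction
#' `fluor_mask_prob` of the fluorescence signals is discarded (re-drawn every
#' epoch), so the model stays usable when the modality is missing.
#'
#' @param class_names Ordered class names; must include a droplet class so
#'   the model can separate water droplets from pollen.
#' @param image_side Input image side length in pixels; must be divisible by
#'   `2^length(conv_channels)`.
#' @param conv_channels Integer vector of feature-map counts, one per block.
#' @param fluor_hidden_units Units in the fluorescence branch (>= 1).
#' @param fluor_mask_prob Fluorescence-dropout probability in \[0,1\]
#'   (default 0.2).
#' @param epochs,learning_rate,batch_size Training-loop parameters.
#' @param rng_seed Seed for weight initialisation, shuffling and masking.
#' @return A `model_config` object.
#' @export
model_config <- function(class_names,
                         image_side = 200L,
                         conv_channels = c(16L, 32L, 64L),
                         fluor_hidden_units = 8L,
                         fluor_mask_prob = 0.2,
                         epochs = 10L, learning_rate = 1e-3,
                         batch_size = 32L, rng_seed = 1L) {
  if (length(class_names) < 2L || anyDuplicated(class_names))
    stop_invalid("`class_names` must be >= 2 distinct names")
  if (length(conv_channels) < 1L || any(conv_channels < 1))
    stop_invalid("at least one convolution block is required")
  image_side <- as.integer(image_side)
  if (image_side %% (2^length(conv_channels)) != 0)
    stop_invalid(sprintf(
      "`image_side` (%d) must be divisible by 2^%d for %d pooling stages",
      image_side, length(conv_channels), length(conv_channels)),
      class = "holopollen_config_error")
  if (fluor_mask_prob < 0 || fluor_mask_prob > 1)
    stop_invalid("`fluor_mask_prob` must be in [0,1]")
  if (fluor_hidden_units < 1) stop_invalid("`fluor_hidden_units` must be >= 1")
  structure(list(class_names = as.character(class_names),
                 image_side = image_side,
                 conv_channels = as.integer(conv_channels),
                 fluor_hidden_units = as.integer(fluor_hidden_units),
                 fluor_mask_prob = as.numeric(fluor_mask_prob),
                 epochs = as.integer(epochs),
                 learning_rate = as.numeric(learning_rate),
                 batch_size = as.integer(batch_size),
                 rng_seed = as.integer(rng_seed)),
            class = "model_config")
}

#' Build an untrained two-branch model
#'
#' Weights are initialised from scratch (He-scaled normals seeded by
#' `config$rng_seed`); no pre-trained network is involved. Absent
#' fluorescence is encoded as a zero 13-vector with presence flag 0, so a
#' record without the modality and one with explicit zeros + flag 0 produce
#' identical outputs by construction.
#'
#' @param config A [model_config()].
#' @return A `pollen_model` object.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "model_config"))
  S <- config$image_side
  ch <- config$conv_channels
  B <- length(ch)
  params <- local_seed(config$rng_seed, {
    p <- list()
    cin <- 2L
    for (b in seq_len(B)) {
      p[[sprintf("b%d_W1", b)]] <- he_mat(ch[b], cin * 9L)
      p[[sprintf("b%d_b1", b)]] <- numeric(ch[b])
      p[[sprintf("b%d_W2", b)]] <- he_mat(ch[b], ch[b] * 9L)
      p[[sprintf("b%d_b2", b)]] <- numeric(ch[b])
      cin <- ch[b]
    }
    h <- config$fluor_hidden_units
    nflat <- ch[B] * (S / 2^B)^2
    p$Wf <- he_mat(h, 14L)
    p$bf <- numeric(h)
    p$Wo <- he_mat(length(config$class_names), nflat + h)
    p$bo <- numeric(length(config$class_names))
    p
  })
  structure(list(params = params, config = config,
                 class_names = config$class_names,
                 trained = FALSE, report = NULL),
            class = "pollen_model")
}

he_mat <- function(nr, nc) matrix(rnorm(nr * nc, 0, sqrt(2 / nc)), nr, nc)

#' @export
print.pollen_model <- function(x, ...) {
  cat(sprintf("<pollen_model> %s; %d px, blocks [%s], %d fluor units; %s\n",
              paste(x$class_names, collapse = "/"), x$config$image_side,
              paste(x$config$conv_channels, collapse = ","),
              x$config$fluor_hidden_units,
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

# Encode events into the dense inputs of the network: images as a
# (2*S*S x N) matrix, fluorescence as (14 x N) = 13 channels + presence flag
# (absent -> zeros + flag 0).
encode_events <- function(events, image_side) {
  n <- nrow(events)
  Ximg <- matrix(0, 2 * image_side^2, n)
  Xfl <- matrix(0, 14, n)
  for (i in seq_len(n)) {
    h1 <- events$hologram1[[i]]
    if (nrow(h1) != image_side)
      stop_invalid(sprintf(
        "event %s: image side %d does not match the model's %d",
        events$event_id[i], nrow(h1), image_side),
        class = "holopollen_config_error")
    Ximg[, i] <- c(as.vector(h1), as.vector(events$hologram2[[i]]))
    fl <- events$fluorescence[[i]]
    if (!is.null(fl)) Xfl[, i] <- c(fl, 1)
  }
  list(img = Ximg, fl = Xfl)
}

#' Discard fluorescence signals from a batch of events
#'
#' Each event's fluorescence vector is independently replaced by "absent"
#' with probability `p`; events already lacking the modality stay absent.
#' This is the operation applied (re-drawn each epoch) during training.
#'
#' @param events Event tibble.
#' @param p Masking probability in \[0,1\].
#' @param rng_seed Integer seed; decisions are reproducible.
#' @return The event tibble with masked `fluorescence` entries.
#' @export
mask_fluorescence_batch <- function(events, p, rng_seed) {
  if (!is.numeric(p) || p < 0 || p > 1) stop_invalid("`p` must be in [0,1]")
  drop <- local_seed(rng_seed, runif(nrow(events)) < p)
  events$fluorescence[drop] <- list(NULL)
  events
}

#' Train the two-branch model
#'
#' Minimises the cross-entropy with minibatch Adam; the fluorescence-dropout
#' mask (rate `config$fluor_mask_prob`) is re-drawn at every epoch. Training
#' is deterministic given `config$rng_seed`. Events are expected to have
#' passed the morphological prefilter.
#'
#' @param model A `pollen_model` from [build_model()].
#' @param train_events Labelled event tibble (`true_label` set, all labels in
#'   the model's `class_names`).
#' @param val_events Optional held-out labelled events; per-epoch accuracy is
#'   recorded in the training report.
#' @return The trained `pollen_model`; `$report` holds the per-epoch tibble
#'   (`epoch`, `loss`, `val_accuracy`) plus the config hash and seed.
#' @export
train_model <- function(model, train_events, val_events = NULL) {
  stopifnot(inherits(model, "pollen_model"))
  cfg <- model$config
  check_labels <- function(ev, what) {
    if (anyNA(ev$true_label))
      stop_data(paste(what, "events must all be labelled"))
    bad <- setdiff(unique(ev$true_label), model$class_names)
    if (length(bad))
      stop_data(paste0(what, " labels outside class_names: ",
                       paste(bad, collapse = ", ")))
  }
  check_labels(train_events, "training")
  enc <- encode_events(train_events, cfg$image_side)
  y <- match(train_events$true_label, model$class_names)
  if (!is.null(val_events) && nrow(val_events)) {
    check_labels(val_events, "validation")
    venc <- encode_events(val_events, cfg$image_side)
    yv <- match(val_events$true_label, model$class_names)
  } else {
    venc <- list(img = matrix(0, 2 * cfg$image_side^2, 0),
                 fl = matrix(0, 14, 0))
    yv <- integer(0)
  }
  fit <- nn_train_cpp(model$params, enc$img, enc$fl, y,
                      venc$img, venc$fl, yv,
                      cfg$conv_channels, cfg$image_side,
                      cfg$epochs, cfg$learning_rate, cfg$batch_size,
                      cfg$fluor_mask_prob, cfg$rng_seed)
  model$params <- fit$params
  model$trained <- TRUE
  model$report <- tibble::tibble(epoch = seq_len(cfg$epochs),
                                 loss = as.numeric(fit$epoch_loss),
                                 val_accuracy = as.numeric(fit$val_acc))
  attr(model$report, "config_hash") <- config_hash(unclass(cfg))
  attr(model$report, "seed") <- cfg$rng_seed
  model
}

# Raw logits for a batch of events (used by the export round-trip checks).
model_logits <- function(model, events) {
  enc <- encode_events(events, model$config$image_side)
  nn_forward_cpp(model$params, enc$img, enc$fl,
                 model$config$conv_channels, model$config$image_side)
}

#' Classify events
#'
#' Returns one prediction per event: the class-probability vector (softmax
#' over the model's classes), and the confidence, defined as the maximum
#' class probability. Missing fluorescence is handled through the
#' zeros + presence-flag encoding.
#'
#' @param object A `pollen_model`.
#' @param events Event tibble (prefilter-accepted).
#' @param ... Unused.
#' @return Tibble with `event_id`, `probs` (list of named numeric vectors
#'   summing to 1) and `confidence`.
#' @export
predict.pollen_model <- function(object, events, ...) {
  logits <- model_logits(object, events)
  pm <- apply(logits, 2, function(z) {
    p <- exp(z - max(z))
    p / sum(p)
  })
  pm <- matrix(pm, nrow = length(object$class_names))
  tibble::tibble(
    event_id = events$event_id,
    probs = lapply(seq_len(ncol(pm)),
                   function(i) setNames(pm[, i], object$class_names)),
    confidence = if (ncol(pm)) apply(pm, 2, max) else numeric(0))
}

#' Resolve predictions at a confidence threshold
#'
#' An event is assigned its highest-probability class iff the confidence is
#' at least `c` and the maximum is unique; otherwise it is left
#' `"UNCLASSIFIED"` (conservative abstention; ties abstain).
#'
#' @param predictions Prediction tibble from [predict.pollen_model()].
#' @param c Confidence threshold in \[0,1\].
#' @return The prediction tibble with a `label` column added.
#' @export
apply_confidence_threshold <- function(predictions, c) {
  if (!is.numeric(c) || length(c) != 1L || c < 0 || c > 1)
    stop_invalid("threshold `c` must be a single value in [0,1]")
  predictions$label <- vapply(seq_len(nrow(predictions)), function(i) {
    p <- predictions$probs[[i]]
    m <- max(p)
    if (m >= c && sum(p == m) == 1L) names(p)[which.max(p)] else "UNCLASSIFIED"
  }, character(1))
  predictions
}
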