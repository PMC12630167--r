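#' Write / read an event dataset on disk
#'
#' Events are stored as one greyscale PNG per hologram under `images/`, one
#' JSON object per event in `events.jsonl`, and a `manifest.json` recording
#' the file references, labels, generator configuration hash and random
#' seed. The round trip is lossless for all metadata; hologram intensities
#' are quantised to the PNG bit depth.
#'
#' @param events Event tibble (see [validate_events()]).
#' @param dir Dataset directory (created if needed).
#' @param manifest Optional manifest list from [generate_event_stream()];
#'   its seed and configuration hash are carried into `manifest.json`.
#' @return `write_events()` returns `dir` invisibly; `read_events()` returns
#'   the event tibble.
#' @export
write_events <- function(events, dir, manifest = NULL) {
  validate_events(events)
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  recs <- character(nrow(events))
  files <- character(0)
  for (i in seq_len(nrow(events))) {
    id <- events$event_id[i]
    p1 <- file.path("images", paste0(id, "_1.png"))
    p2 <- file.path("images", paste0(id, "_2.png"))
    png::writePNG(events$hologram1[[i]], file.path(dir, p1))
    png::writePNG(events$hologram2[[i]], file.path(dir, p2))
    files <- c(files, p1, p2)
    recs[i] <- jsonlite::toJSON(list(
      event_id = id,
      timestamp = format(events$timestamp[i], "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC"),
      site = events$site[i],
      images = c(p1, p2),
      fluorescence = events$fluorescence[[i]],
      true_label = events$true_label[i],
      pixel_scale = events$pixel_scale[i]), auto_unbox = TRUE, null = "null",
      digits = NA)
  }
  writeLines(recs, file.path(dir, "events.jsonl"))
  man <- list(n_events = nrow(events), files = files,
              labels = as.list(table(events$true_label)),
              seed = manifest$seed, config_hash = manifest$config_hash)
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(dir)
}

#' @rdname write_events
#' @export
read_events <- function(dir) {
  meta_path <- file.path(dir, "events.jsonl")
  if (!file.exists(meta_path)) stop_data(paste("no events.jsonl in", dir))
  lines <- readLines(meta_path)
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e) stop_data(sprintf(
                      "events.jsonl line %d: malformed JSON (%s)",
                      i, conditionMessage(e)),
                      class = "holopollen_parse_error"))
    for (f in c("event_id", "timestamp", "site", "images", "pixel_scale"))
      if (is.null(rec[[f]]))
        stop_data(sprintf("events.jsonl line %d: missing field '%s'", i, f),
                  class = "holopollen_parse_error")
    imgs <- file.path(dir, rec$images)
    if (!all(file.exists(imgs)))
      stop_data(sprintf("manifest integrity: missing image file(s) for event %s",
                        rec$event_id), class = "holopollen_manifest_error")
    h <- lapply(imgs, function(p) {
      m <- png::readPNG(p)
      if (length(dim(m)) == 3L) m <- m[, , 1]
      m
    })
    rows[[i]] <- tibble::tibble(
      event_id = rec$event_id,
      timestamp = as.POSIXct(rec$timestamp, tz = "UTC",
                             format = "%Y-%m-%dT%H:%M:%OSZ"),
      site = rec$site,
      hologram1 = list(h[[1]]), hologram2 = list(h[[2]]),
      fluorescence = list(if (is.null(rec$fluorescence)) NULL
                          else as.numeric(rec$fluorescence)),
      true_label = rec$true_label %||% NA_character_,
      pixel_scale = rec$pixel_scale)
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else empty_events()
  validate_events(out)
  out
}

series_header <- c("site", "taxon", "resolution", "timestamp", "value", "source")

#' Write / read concentration series as CSV
#'
#' The CSV has the fixed header
#' `site,taxon,resolution,timestamp,value,source` with ISO-8601 UTC
#' timestamps. Reading validates the invariants (non-negative finite values,
#' known resolution and source) and reports the offending line and field.
#'
#' @param series Concentration-series tibble (possibly several site/taxon
#'   groups stacked).
#' @param path CSV file path.
#' @export
write_series <- function(series, path) {
  df <- as.data.frame(series)[, series_header]
  df$timestamp <- format(df$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  if (!file.exists(path)) stop_data(paste("no such file:", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), series_header))
    stop_data(sprintf("%s: header must be '%s'", path,
                      paste(series_header, collapse = ",")),
              class = "holopollen_parse_error")
  for (i in seq_len(nrow(df))) {
    if (!is.finite(df$value[i]) || df$value[i] < 0)
      stop_data(sprintf("%s line %d, field 'value': must be finite and >= 0 (got %s)",
                        path, i + 1L, df$value[i]),
                class = "holopollen_parse_error")
    if (!df$resolution[i] %in% c("daily", "hourly"))
      stop_data(sprintf("%s line %d, field 'resolution': unknown value '%s'",
                        path, i + 1L, df$resolution[i]),
                class = "holopollen_parse_error")
    if (!df$source[i] %in% c("manual", "automatic", "true"))
      stop_data(sprintf("%s line %d, field 'source': unknown value '%s'",
                        path, i + 1L, df$source[i]),
                class = "holopollen_parse_error")
  }
  ts <- as.POSIXct(df$timestamp, tz = "UTC", format = "%Y-%m-%dT%H:%M:%SZ")
  if (anyNA(ts) && nrow(df))
    stop_data(sprintf("%s line %d, field 'timestamp': not ISO-8601 UTC",
                      path, which(is.na(ts))[1] + 1L),
              class = "holopollen_parse_error")
  out <- tibble::as_tibble(df)
  out$timestamp <- ts
  out
}

#' Write / read taxon profiles as YAML
#'
#' @param profiles Named list of [taxon_profile()]s.
#' @param path YAML file path.
#' @export
write_profiles_yaml <- function(profiles, path) {
  yaml::write_yaml(lapply(profiles, unclass), path, precision = 15L)
  invisible(path)
}

#' @rdname write_profiles_yaml
#' @export
read_profiles_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(p) do.call(taxon_profile, p))
}
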