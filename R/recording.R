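# SignalRecording: the package's container for multichannel, multi-rate
# wearable-sensor recordings. Channels may have different sampling rates
# (e.g. sEMG at 2000 Hz, IMU at 200 Hz); all share a time origin at 0 s.

#' Construct a multichannel signal recording
#'
#' @param channels named list of numeric sample vectors.
#' @param meta data.frame with one row per channel and columns `name`,
#'   `modality` (one of `"emg"`, `"acc"`, `"gyr"`, `"joint"`), `rate` (Hz),
#'   `sensor` (grouping id for tri-axial units; `NA` for single channels) and
#'   `axis` (`"x"`, `"y"`, `"z"` or `NA`).
#' @param labels data.frame with columns `start`, `end` (seconds) and
#'   `activity`; intervals must not overlap.
#' @param standing_phase numeric `c(start, end)` in seconds of the quiet
#'   standing calibration phase, or `NULL`. Must span at least 1 s.
#' @param lying_phase optional `c(start, end)` of a lying calibration phase.
#' @return An object of class `SignalRecording`.
#' @export
signal_recording <- function(channels, meta, labels = NULL,
                             standing_phase = NULL, lying_phase = NULL) {
  if (!is.list(channels) || is.null(names(channels)) || any(names(channels) == ""))
    stop_gfsfan("channels must be a named list of numeric vectors")
  req <- c("name", "modality", "rate")
  if (!is.data.frame(meta) || !all(req %in% names(meta)))
    stop_gfsfan("meta must be a data.frame with columns name, modality, rate")
  if (!"sensor" %in% names(meta)) meta$sensor <- NA_character_
  if (!"axis" %in% names(meta)) meta$axis <- NA_character_
  if (!setequal(meta$name, names(channels)))
    stop_gfsfan("meta rows must match channel names; missing: ",
                paste(setdiff(names(channels), meta$name), collapse = ", "))
  meta <- meta[match(names(channels), meta$name), , drop = FALSE]
  rownames(meta) <- NULL
  bad <- !meta$modality %in% c("emg", "acc", "gyr", "joint")
  if (any(bad)) stop_gfsfan("unknown modality: ", paste(unique(meta$modality[bad]), collapse = ", "))
  if (any(!is.finite(meta$rate)) || any(meta$rate <= 0))
    stop_gfsfan("sampling rates must be positive and finite")
  for (nm in names(channels)) {
    x <- channels[[nm]]
    if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
      stop_gfsfan("channel '", nm, "' contains non-finite samples")
  }
  if (!is.null(labels)) {
    if (!is.data.frame(labels) || !all(c("start", "end", "activity") %in% names(labels)))
      stop_gfsfan("labels must have columns start, end, activity")
    labels <- labels[order(labels$start), , drop = FALSE]
    rownames(labels) <- NULL
    if (nrow(labels) > 1 && any(labels$start[-1] < labels$end[-nrow(labels)] - 1e-9))
      stop_gfsfan("label intervals overlap")
    if (any(labels$end <= labels$start)) stop_gfsfan("label intervals must have end > start")
  } else {
    labels <- data.frame(start = numeric(0), end = numeric(0),
                         activity = character(0))
  }
  if (!is.null(standing_phase)) {
    if (length(standing_phase) != 2 || diff(standing_phase) < 1)
      stop_gfsfan("standing_phase must be c(start, end) spanning at least 1 s")
  }
  structure(list(channels = channels, meta = meta, labels = labels,
                 standing_phase = standing_phase, lying_phase = lying_phase),
            class = "SignalRecording")
}

#' @export
print.SignalRecording <- function(x, ...) {
  cat("SignalRecording:", length(x$channels), "channels,",
      sprintf("%.2f s\n", recording_duration(x)))
  m <- x$meta
  m$n <- vapply(x$channels, length, 0L)
  print(m, row.names = FALSE)
  if (nrow(x$labels)) cat(nrow(x$labels), "label intervals:",
                          paste(unique(x$labels$activity), collapse = ", "), "\n")
  if (!is.null(x$standing_phase))
    cat(sprintf("standing phase: [%.2f, %.2f] s\n",
                x$standing_phase[1], x$standing_phase[2]))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec a `SignalRecording`.
#' @return Duration of the longest channel, seconds.
#' @export
recording_duration <- function(rec) {
  max(vapply(seq_along(rec$channels),
             function(i) length(rec$channels[[i]]) / rec$meta$rate[i], 0))
}

channel_slice <- function(rec, name, t0, t1) {
  i <- match(name, rec$meta$name)
  rate <- rec$meta$rate[i]
  x <- rec$channels[[name]]
  i0 <- max(1L, floor(t0 * rate) + 1L)
  i1 <- min(length(x), ceiling(t1 * rate))
  x[i0:i1]
}

# mean sample over a time interval for each channel of a sensor, in x/y/z order
sensor_triplet <- function(rec, sensor, modality) {
  sel <- which(rec$meta$sensor %in% sensor & rec$meta$modality == modality)
  sel <- sel[order(rec$meta$axis[sel])]
  if (length(sel) != 3)
    stop_gfsfan("sensor '", sensor, "' does not have 3 ", modality, " axes")
  rec$meta$name[sel]
}
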