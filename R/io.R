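# Plain-text persistence for recordings: one CSV per sampling rate with a
# `time` column and one column per channel, plus a JSON sidecar holding
# channel metadata, label intervals and calibration-phase markers.

sidecar_path <- function(path) sub("\\.csv$", ".json", path)

#' Write a recording to CSV + JSON sidecar
#'
#' Channels sharing a sampling rate are written to one CSV with columns
#' `time, <channel...>`. A recording with several rates produces one CSV per
#' rate (suffix `_<rate>Hz`). The sidecar (same path with `.json`) stores the
#' file list, channel metadata, label intervals and the standing/lying phase
#' markers, and is what [read_recording()] consumes.
#'
#' @param rec a `SignalRecording`.
#' @param path output CSV path (used as the base name).
#' @return Invisibly, the sidecar path.
#' @export
write_recording <- function(rec, path) {
  rates <- sort(unique(rec$meta$rate))
  files <- character(0)
  for (r in rates) {
    nms <- rec$meta$name[rec$meta$rate == r]
    f <- if (length(rates) == 1) path else
      sub("\\.csv$", sprintf("_%gHz.csv", r), path)
    n <- length(rec$channels[[nms[1]]])
    df <- data.frame(time = (seq_len(n) - 1) / r)
    for (nm in nms) df[[nm]] <- rec$channels[[nm]]
    write.csv(df, f, row.names = FALSE)
    files <- c(files, basename(f))
  }
  side <- list(
    files = as.list(files),
    channels = lapply(seq_len(nrow(rec$meta)), function(i) {
      m <- rec$meta[i, ]
      list(name = m$name, modality = m$modality, rate = m$rate,
           sensor = if (is.na(m$sensor)) NULL else m$sensor,
           axis = if (is.na(m$axis)) NULL else m$axis)
    }),
    labels = if (nrow(rec$labels)) lapply(seq_len(nrow(rec$labels)), function(i)
      list(start = rec$labels$start[i], end = rec$labels$end[i],
           activity = rec$labels$activity[i])) else list(),
    standing_phase = rec$standing_phase,
    lying_phase = rec$lying_phase)
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(sidecar_path(path))
}

#' Read a recording written by [write_recording()]
#'
#' Validates that each CSV's time column increases at a constant rate and
#' that the sidecar declares every channel; a time-stamp gap is reported with
#' its row index.
#'
#' @param path the CSV path given to [write_recording()].
#' @return A `SignalRecording`.
#' @export
read_recording <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) stop_gfsfan("sidecar not found: ", sp)
  side <- jsonlite::read_json(sp)
  if (!"standing_phase" %in% names(side))
    stop_gfsfan("sidecar ", sp, " is missing required key 'standing_phase'")
  meta <- do.call(rbind, lapply(side$channels, function(ch) data.frame(
    name = ch$name, modality = ch$modality, rate = as.numeric(ch$rate),
    sensor = ch$sensor %||% NA_character_, axis = ch$axis %||% NA_character_,
    stringsAsFactors = FALSE)))
  channels <- list()
  for (f in unlist(side$files)) {
    fp <- file.path(dirname(path), f)
    if (!file.exists(fp)) stop_gfsfan("recording file missing: ", fp)
    df <- read.csv(fp, check.names = FALSE)
    if (!"time" %in% names(df)) stop_gfsfan(fp, ": no 'time' column")
    tm <- df$time
    if (length(tm) >= 2) {
      dt <- diff(tm)
      if (any(dt <= 0))
        stop_gfsfan(fp, ": time not monotone increasing at row ",
                    which(dt <= 0)[1] + 1L)
      if (any(abs(dt - dt[1]) > 1e-6 * max(dt[1], 1e-12)))
        stop_gfsfan(fp, ": time-stamp gap at row ",
                    which(abs(dt - dt[1]) > 1e-6 * max(dt[1], 1e-12))[1] + 1L)
    }
    for (nm in setdiff(names(df), "time")) {
      if (!nm %in% meta$name)
        stop_gfsfan(fp, ": channel '", nm, "' not declared in sidecar")
      channels[[nm]] <- df[[nm]]
    }
  }
  missing <- setdiff(meta$name, names(channels))
  if (length(missing))
    stop_gfsfan("channels declared in sidecar but absent from CSVs: ",
                paste(missing, collapse = ", "))
  channels <- channels[meta$name]                # sidecar declaration order
  labels <- if (length(side$labels)) do.call(rbind, lapply(side$labels, function(l)
    data.frame(start = as.numeric(l$start), end = as.numeric(l$end),
               activity = l$activity, stringsAsFactors = FALSE))) else NULL
  signal_recording(channels, meta, labels,
                   standing_phase = if (!is.null(side$standing_phase))
                     as.numeric(unlist(side$standing_phase)),
                   lying_phase = if (!is.null(side$lying_phase))
                     as.numeric(unlist(side$lying_phase)))
}
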