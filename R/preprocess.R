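# Preprocessing: modality-specific filtering, standing-phase normalization
# and sliding-window segmentation.
#
# All filters are Butterworth designs applied zero-phase (forward-backward
# via signal::filtfilt), appropriate for offline window processing; a pure
# tone passes with no phase shift.

default_preprocess_config <- function() {
  list(emg_band = c(10, 500), emg_order = 4, emg_smooth_ms = 50,
       acc_lowpass = 10, acc_order = 8, gyr_lowpass = 30, gyr_order = 8,
       normalize_standing = TRUE)
}

butter_filtfilt <- function(x, order, cutoff, rate, type) {
  W <- cutoff / (rate / 2)
  if (any(W <= 0) || any(W >= 1))
    stop_gfsfan("configuration error: cutoff ", paste(cutoff, collapse = "-"),
                " Hz infeasible at rate ", rate, " Hz")
  bf <- signal::butter(order, W, type = type)
  signal::filtfilt(bf, x)
}

moving_average <- function(x, k) {
  if (k <= 1) return(x)
  if (k %% 2 == 0) k <- k + 1L           # centered window
  pad <- (k - 1) / 2
  xp <- c(rep(x[1], pad), x, rep(x[length(x)], pad))
  as.numeric(stats::filter(xp, rep(1 / k, k), sides = 2))[(pad + 1):(pad + length(x))]
}

#' Filter and normalize a recording
#'
#' sEMG channels are band-pass filtered (4th-order Butterworth, 10-500 Hz by
#' default) and smoothed with a centered 50 ms moving average. Accelerometer
#' channels are low-pass filtered at 10 Hz (8th order) and, when standing
#' normalization is enabled, divided by the mean resultant (vector-norm)
#' acceleration of their sensor over the standing phase, so resultant
#' acceleration at rest is ~1. Gyroscope channels are low-pass filtered at
#' 30 Hz (8th order) and the per-axis standing mean is subtracted (static
#' bias removal). A user-supplied ellipsoid calibration can be hooked in via
#' `config$imu_correction`, a function applied to each IMU channel before
#' filtering.
#'
#' @param rec a `SignalRecording`.
#' @param config list overriding any of the defaults: `emg_band`,
#'   `emg_order`, `emg_smooth_ms`, `acc_lowpass`, `acc_order`, `gyr_lowpass`,
#'   `gyr_order`, `normalize_standing`, `imu_correction`.
#' @return A preprocessed `SignalRecording`.
#' @export
preprocess <- function(rec, config = list()) {
  stopifnot(inherits(rec, "SignalRecording"))
  cfg <- utils::modifyList(default_preprocess_config(), config)
  if (cfg$normalize_standing && is.null(rec$standing_phase))
    stop_gfsfan("standing-phase normalization requested but the recording ",
                "has no standing_phase")
  out <- rec$channels
  for (i in seq_len(nrow(rec$meta))) {
    nm <- rec$meta$name[i]; mod <- rec$meta$modality[i]; rate <- rec$meta$rate[i]
    x <- out[[nm]]
    if (mod %in% c("acc", "gyr") && !is.null(cfg$imu_correction))
      x <- cfg$imu_correction(x, nm)
    x <- switch(mod,
      emg = {
        y <- butter_filtfilt(x, cfg$emg_order, cfg$emg_band, rate, "pass")
        moving_average(y, round(cfg$emg_smooth_ms / 1000 * rate))
      },
      acc = butter_filtfilt(x, cfg$acc_order, cfg$acc_lowpass, rate, "low"),
      gyr = butter_filtfilt(x, cfg$gyr_order, cfg$gyr_lowpass, rate, "low"),
      x)
    out[[nm]] <- x
  }
  if (cfg$normalize_standing) {
    sp <- rec$standing_phase
    for (sens in unique(rec$meta$sensor[rec$meta$modality == "acc"])) {
      if (is.na(sens)) next
      nms <- rec$meta$name[rec$meta$sensor %in% sens & rec$meta$modality == "acc"]
      rate <- rec$meta$rate[match(nms[1], rec$meta$name)]
      i0 <- floor(sp[1] * rate) + 1; i1 <- floor(sp[2] * rate)
      res <- sqrt(Reduce(`+`, lapply(nms, function(nm) out[[nm]][i0:i1]^2)))
      scale <- mean(res)
      if (scale <= 0) stop_gfsfan("zero resultant acceleration in standing phase")
      for (nm in nms) out[[nm]] <- out[[nm]] / scale
    }
    for (i in which(rec$meta$modality == "gyr")) {
      nm <- rec$meta$name[i]; rate <- rec$meta$rate[i]
      i0 <- floor(sp[1] * rate) + 1; i1 <- floor(sp[2] * rate)
      out[[nm]] <- out[[nm]] - mean(out[[nm]][i0:i1])
    }
  }
  rec$channels <- out
  rec
}

#' Segment a recording into sliding windows
#'
#' Windows advance by `window_ms * (1 - overlap)` in time; each window takes
#' `round(window_ms * rate / 1000)` samples from every channel, so channels
#' of different rates stay aligned. A window's label is the activity covering
#' the majority of its time span (ties broken toward the earlier label);
#' windows with no labelled majority or overlapping the standing calibration
#' phase are dropped.
#'
#' @param rec a `SignalRecording`.
#' @param window_ms window length in milliseconds.
#' @param overlap overlap fraction in `[0, 1)`.
#' @param drop_unlabelled drop windows whose majority is unlabelled
#'   (default `TRUE`).
#' @return An object of class `WindowSet`: list with `epochs` (each holding
#'   `data` per channel, `label`, `start`), `window_ms`, `overlap`, `meta`.
#' @export
segment <- function(rec, window_ms, overlap = 0.8, drop_unlabelled = TRUE) {
  stopifnot(inherits(rec, "SignalRecording"))
  if (overlap < 0 || overlap >= 1) stop_gfsfan("overlap must be in [0, 1)")
  dur_ms <- recording_duration(rec) * 1000
  if (window_ms > dur_ms) stop_gfsfan("window (", window_ms,
                                      " ms) longer than recording")
  step_ms <- window_ms * (1 - overlap)
  nwin_samp <- round(window_ms * rec$meta$rate / 1000)
  names(nwin_samp) <- rec$meta$name
  starts <- seq(0, dur_ms - window_ms, by = step_ms) / 1000
  epochs <- list()
  for (s in starts) {
    e <- s + window_ms / 1000
    if (!is.null(rec$standing_phase) &&
        s < rec$standing_phase[2] - 1e-9 && e > rec$standing_phase[1] + 1e-9)
      next
    lab <- window_label(rec$labels, s, e)
    if (is.na(lab) && drop_unlabelled) next
    data <- list()
    ok <- TRUE
    for (i in seq_len(nrow(rec$meta))) {
      nm <- rec$meta$name[i]
      i0 <- round(s * rec$meta$rate[i]) + 1
      i1 <- i0 + nwin_samp[[nm]] - 1
      if (i1 > length(rec$channels[[nm]])) { ok <- FALSE; break }
      data[[nm]] <- rec$channels[[nm]][i0:i1]
    }
    if (!ok) next
    epochs[[length(epochs) + 1]] <- list(data = data, label = lab, start = s)
  }
  structure(list(epochs = epochs, window_ms = window_ms, overlap = overlap,
                 meta = rec$meta),
            class = "WindowSet")
}

# plurality-coverage label of [s, e]; ties broken toward the earlier label;
# NA when unlabelled time outweighs the best label
window_label <- function(labels, s, e) {
  if (!nrow(labels)) return(NA_character_)
  cover <- pmax(0, pmin(labels$end, e) - pmax(labels$start, s))
  m <- which.max(cover)                 # labels sorted by start: first = earlier
  unlabelled <- (e - s) - sum(cover)
  if (cover[m] == 0 || unlabelled > cover[m] + 1e-9) return(NA_character_)
  labels$activity[m]
}

#' @export
print.WindowSet <- function(x, ...) {
  labs <- vapply(x$epochs, function(e) e$label, "")
  cat("WindowSet:", length(x$epochs), "windows of", x$window_ms, "ms,",
      sprintf("overlap %.0f%%\n", 100 * x$overlap))
  if (length(labs)) print(table(labs))
  invisible(x)
}
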