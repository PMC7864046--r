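# The feature bank: time-domain, frequency-domain and wavelet-domain
# features per channel, plus per-sensor features (axis correlations, Jerk,
# signal magnitude area) for tri-axial units, assembled into the fixed
# modality layout used for activity recognition.
#
# The noise gates delta_z, delta_s, delta_w for ZC/SSC/WAMP default to 1% of
# the window RMS — a noise-floor-relative setting standard in the EMG
# feature literature; absolute values can be supplied instead.

default_feature_params <- function() {
  list(delta_z = NULL, delta_s = NULL, delta_w = NULL, delta_rel = 0.01,
       ar_order = 4, wavelet_mode = "symmetric")
}

resolve_delta <- function(delta, x, rel) delta %||% (rel * sqrt(mean(x^2)))

#' Time-domain features of one window
#'
#' Computes MV, SD, VAR, RMS, SKE, KUR, IQR, P2P, MAV, WL, ZC, SSC, WAMP,
#' LD, ARC (4 Burg autoregressive coefficients), Energy and MMAV. Skewness
#' and kurtosis of a constant window are returned as 0 (flagged); a singular
#' AR fit yields zero coefficients (flagged). Flags are attached as
#' attribute `"flags"`.
#'
#' @param x numeric window (length >= 8).
#' @param params list overriding [default_feature_params()]: `delta_z`,
#'   `delta_s`, `delta_w` (absolute gates) or `delta_rel` (fraction of the
#'   window RMS used when a gate is `NULL`), `ar_order`.
#' @return Named numeric vector of 20 values.
#' @export
compute_td <- function(x, params = list()) {
  p <- utils::modifyList(default_feature_params(), params)
  N <- length(x)
  if (N < 8) stop_gfsfan("window too short for time-domain features (need >= 8)")
  flags <- character(0)
  mv <- mean(x)
  sdv <- sd(x)
  varv <- sdv^2
  rms <- sqrt(mean(x^2))
  if (sdv == 0) {
    ske <- kur <- 0
    flags <- c(flags, "SKE_constant", "KUR_constant")
  } else {
    ske <- sum((x - mv)^3) / (N * sdv^3)
    kur <- sum((x - mv)^4) / (N * sdv^4)
  }
  q <- quantile(x, c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  p2p <- max(x) - min(x)
  mav <- mean(abs(x))
  dx <- diff(x)
  wl <- sum(abs(dx))
  dz <- resolve_delta(p$delta_z, x, p$delta_rel)
  ds <- resolve_delta(p$delta_s, x, p$delta_rel)
  dw <- resolve_delta(p$delta_w, x, p$delta_rel)
  zc <- sum(x[-N] * x[-1] < 0 & abs(dx) > dz)
  i <- 2:(N - 1)
  ssc <- sum((x[i] - x[i - 1]) * (x[i] - x[i + 1]) > 0 &
               abs(x[i] - x[i + 1]) > ds & abs(x[i] - x[i - 1]) > ds)
  wamp <- sum(abs(dx) > dw)
  ld <- exp(mean(log(abs(x))))
  if (!is.finite(ld)) { ld <- 0; flags <- c(flags, "LD_zero_sample") }
  arc <- tryCatch({
    fit <- ar(x, aic = FALSE, order.max = p$ar_order, method = "burg")
    a <- fit$ar
    if (length(a) < p$ar_order || anyNA(a)) stop("short")
    a
  }, error = function(e) {
    flags <<- c(flags, "ARC_singular")
    rep(0, p$ar_order)
  })
  energy <- mean(x^2)
  w <- as.numeric(seq_len(N) >= 0.25 * N & seq_len(N) <= 0.75 * N)
  mmav <- mean(w * abs(x))
  out <- c(MV = mv, SD = sdv, VAR = varv, RMS = rms, SKE = ske, KUR = kur,
           IQR = iqr, P2P = p2p, MAV = mav, WL = wl, ZC = zc, SSC = ssc,
           WAMP = wamp, LD = ld,
           ARC1 = arc[1], ARC2 = arc[2], ARC3 = arc[3], ARC4 = arc[4],
           Energy = energy, MMAV = mmav)
  attr(out, "flags") <- flags
  out
}

#' Frequency-domain features of one window
#'
#' One-sided magnitude spectrum from the FFT, DC excluded, no zero padding.
#' MPF is the power-weighted mean frequency; MDF, F25 and F75 split the
#' cumulative power 1:1, 1:3 and 3:1; Entropy is the Shannon entropy of the
#' normalized power spectrum; 3LVD holds the three largest spectral
#' magnitudes in descending order. An all-zero window yields zeros (flagged).
#'
#' @param x numeric window (length >= 16).
#' @param rate sampling rate, Hz.
#' @return Named numeric vector `MPF, MDF, F25, F75, Entropy, LVD1..LVD3`.
#' @export
compute_fd <- function(x, rate) {
  N <- length(x)
  if (N < 16) stop_gfsfan("window too short for frequency-domain features")
  X <- fft(x)
  bins <- 2:(floor(N / 2) + 1)                   # one-sided, DC excluded
  m <- Mod(X[bins])
  freq <- (bins - 1) * rate / N
  pw <- m^2
  tot <- sum(pw)
  flags <- character(0)
  if (tot == 0) {
    out <- c(MPF = 0, MDF = 0, F25 = 0, F75 = 0, Entropy = 0,
             LVD1 = 0, LVD2 = 0, LVD3 = 0)
    attr(out, "flags") <- "FD_zero_window"
    return(out)
  }
  cp <- cumsum(pw)
  mpf <- sum(pw * freq) / tot
  mdf <- freq[which(cp >= tot / 2)[1]]
  f25 <- freq[which(cp >= tot / 4)[1]]
  f75 <- freq[which(cp >= 3 * tot / 4)[1]]
  ph <- pw / tot
  ent <- -sum(ifelse(ph > 0, ph * log(ph), 0))
  top <- sort(m, decreasing = TRUE)
  top <- c(top, 0, 0, 0)[1:3]
  out <- c(MPF = mpf, MDF = mdf, F25 = f25, F75 = f75, Entropy = ent,
           LVD1 = top[1], LVD2 = top[2], LVD3 = top[3])
  attr(out, "flags") <- flags
  out
}

#' Wavelet-energy features of one window
#'
#' @param x numeric window (long enough for a level-4 sym4 decomposition).
#' @param mode boundary mode (see [wavedec_sym4()]).
#' @return Named numeric vector of the 5 band energies.
#' @export
compute_tfd <- function(x, mode = "symmetric") wavelet_energies(x, mode)

# per-sensor (tri-axial) features
sensor_features <- function(X3, modality) {
  stopifnot(ncol(X3) == 3)
  cc <- function(a, b) {
    if (sd(a) == 0 || sd(b) == 0) return(0)
    cor(a, b)
  }
  out <- c(CCxy = cc(X3[, 1], X3[, 2]), CCxz = cc(X3[, 1], X3[, 3]),
           CCyz = cc(X3[, 2], X3[, 3]))
  if (modality == "acc")
    out <- c(out, Jerk = 0.5 * sum(diff(X3[, 1])^2 + diff(X3[, 2])^2 +
                                     diff(X3[, 3])^2))
  c(out, SMA = mean(abs(X3[, 1]) + abs(X3[, 2]) + abs(X3[, 3])))
}

# per-channel feature layout by modality (the fixed modality grid)
modality_features <- function(modality) {
  td_common <- c("MV", "SD", "VAR", "RMS", "SKE", "KUR", "IQR", "P2P", "MAV",
                 "WL", "LD", "Energy", "MMAV")
  td_spiky <- c("ZC", "SSC", "WAMP")
  fd <- c("MPF", "MDF", "Entropy", "F25", "F75")
  arc <- paste0("ARC", 1:4)
  lvd <- paste0("LVD", 1:3)
  ewc <- c("EWC_A4", "EWC_D4", "EWC_D3", "EWC_D2", "EWC_D1")
  switch(modality,
         emg = c(td_common, td_spiky, arc, fd, lvd, ewc),
         acc = c(td_common, arc, fd, lvd, ewc),
         gyr = c(td_common, td_spiky, arc, fd, lvd, ewc),
         joint = c(td_common, arc, fd, lvd),
         stop_gfsfan("unknown modality: ", modality))
}

modality_sensor_features <- function(modality) {
  switch(modality,
         acc = c("CCxy", "CCxz", "CCyz", "Jerk", "SMA"),
         gyr = c("CCxy", "CCxz", "CCyz", "SMA"),
         character(0))
}

#' Enumerate the feature layout for a sensor inventory
#'
#' Expands the per-channel and per-sensor feature grid over a channel
#' inventory: 33 features per sEMG channel, 30 per accelerometer axis, 33
#' per gyroscope axis, 25 per joint-angle channel, plus 5 per accelerometer
#' unit (3 axis correlations, Jerk, SMA) and 4 per gyroscope unit. For the
#' study inventory (4 sEMG, 3 tri-axial ACC, 3 tri-axial GYR, 2 joint
#' channels) this yields 776 features.
#'
#' @param meta channel inventory: data.frame with columns `name`,
#'   `modality`, and for tri-axial units `sensor` and `axis`.
#' @return data.frame with one row per feature: `name`, `modality`,
#'   `sensor`, `channel`, `feature`, `component`.
#' @export
enumerate_features <- function(meta) {
  if (!"sensor" %in% names(meta)) meta$sensor <- NA_character_
  rows <- list()
  for (i in seq_len(nrow(meta))) {
    feats <- modality_features(meta$modality[i])
    rows[[length(rows) + 1]] <- data.frame(
      name = paste(meta$name[i], feats, sep = "_"),
      modality = meta$modality[i],
      sensor = meta$sensor[i] %||% NA_character_,
      channel = meta$name[i], feature = feats,
      component = seq_along(feats), stringsAsFactors = FALSE)
  }
  for (mod in c("acc", "gyr")) {
    sens <- unique(meta$sensor[meta$modality == mod & !is.na(meta$sensor)])
    for (s in sens) {
      feats <- modality_sensor_features(mod)
      rows[[length(rows) + 1]] <- data.frame(
        name = paste(s, mod, feats, sep = "_"), modality = mod, sensor = s,
        channel = NA_character_, feature = feats,
        component = seq_along(feats), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' The study sensor inventory
#'
#' Four sEMG channels at 2000 Hz (rectus femoris, semitendinosus, tibialis
#' anterior, lateral gastrocnemius), three tri-axial accelerometer and
#' gyroscope units at 200 Hz (low back, thigh, shank) and two joint-angle
#' channels (hip flexion, knee flexion) at 200 Hz.
#'
#' @return Channel metadata data.frame usable with [enumerate_features()].
#' @export
study_sensor_inventory <- function() {
  emg <- data.frame(name = c("LRF", "LSEM", "LTA", "LLGA"), modality = "emg",
                    rate = 2000, sensor = NA_character_, axis = NA_character_,
                    stringsAsFactors = FALSE)
  imu <- do.call(rbind, lapply(c("LB", "LT", "LS"), function(s)
    do.call(rbind, lapply(c("acc", "gyr"), function(m)
      data.frame(name = paste(s, m, c("x", "y", "z"), sep = "_"),
                 modality = m, rate = 200, sensor = s, axis = c("x", "y", "z"),
                 stringsAsFactors = FALSE)))))
  joint <- data.frame(name = c("hip_flexion", "knee_flexion"),
                      modality = "joint", rate = 200, sensor = NA_character_,
                      axis = NA_character_, stringsAsFactors = FALSE)
  rbind(emg, imu, joint)
}

#' Extract the full feature bank from a window set
#'
#' Applies [compute_td()], [compute_fd()] and [compute_tfd()] to every
#' channel of every window according to its modality layout, adds per-sensor
#' features for tri-axial units, and returns the windows x features table
#' with provenance and labels.
#'
#' @param ws a `WindowSet` from [segment()].
#' @param params feature parameters (see [default_feature_params()]).
#' @return A `FeatureTable`.
#' @export
extract_features <- function(ws, params = list()) {
  stopifnot(inherits(ws, "WindowSet"))
  if (!length(ws$epochs)) stop_gfsfan("empty window set")
  p <- utils::modifyList(default_feature_params(), params)
  info <- enumerate_features(ws$meta)
  n <- length(ws$epochs)
  X <- matrix(NA_real_, n, nrow(info))
  colnames(X) <- info$name
  rates <- ws$meta$rate
  names(rates) <- ws$meta$name
  for (w in seq_len(n)) {
    ep <- ws$epochs[[w]]
    vals <- numeric(0)
    for (i in seq_len(nrow(ws$meta))) {
      nm <- ws$meta$name[i]
      x <- ep$data[[nm]]
      feats <- modality_features(ws$meta$modality[i])
      v <- c(compute_td(x, p), compute_fd(x, rates[[nm]]))
      if (any(startsWith(feats, "EWC"))) v <- c(v, compute_tfd(x, p$wavelet_mode))
      vals <- c(vals, stats::setNames(v[feats],
                                      paste(nm, feats, sep = "_")))
    }
    for (mod in c("acc", "gyr")) {
      sens <- unique(ws$meta$sensor[ws$meta$modality == mod &
                                      !is.na(ws$meta$sensor)])
      for (s in sens) {
        nms <- ws$meta$name[ws$meta$sensor %in% s & ws$meta$modality == mod]
        nms <- nms[order(ws$meta$axis[match(nms, ws$meta$name)])]
        X3 <- do.call(cbind, ep$data[nms])
        sv <- sensor_features(X3, mod)
        vals <- c(vals, stats::setNames(sv, paste(s, mod, names(sv), sep = "_")))
      }
    }
    X[w, ] <- vals[colnames(X)]
  }
  labels <- vapply(ws$epochs, function(e) e$label, "")
  feature_table(X, labels, info = info)
}
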