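# Sensor attitude estimation, sensor-to-segment calibration and joint angles.
#
# Conventions: the reference frame has x pointing up (head-ward); a resting
# accelerometer measures the gravity reaction +g along the segment x-axis.
# R_seg^sen (columns x_seg^sen, y_seg^sen, z_seg^sen) maps segment
# coordinates to sensor coordinates; R_sen^ref is the sensor attitude, so
# R_seg^ref = R_sen^ref %*% R_seg^sen.

#' One step of the Mahony complementary attitude filter
#'
#' Integrates angular velocity corrected by the cross-product error between
#' the measured and predicted gravity direction. The proportional gain pulls
#' tilt toward the accelerometer; an optional integral term compensates slow
#' gyro bias. A zero-norm accelerometer sample disables the correction for
#' that step (gyro-only integration).
#'
#' @param q current attitude quaternion `(w, x, y, z)` (`R_sen^ref`).
#' @param gyro angular velocity, rad/s, sensor frame.
#' @param accel specific force, m/s^2, sensor frame.
#' @param dt step, seconds (> 0).
#' @param kp proportional gain (default 0.5).
#' @param ki integral gain (default 0).
#' @param integral accumulated integral error (length 3), used when `ki > 0`.
#' @return The updated unit quaternion; when `ki > 0` the new integral state
#'   is attached as attribute `"integral"`.
#' @export
mahony_update <- function(q, gyro, accel, dt, kp = 0.5, ki = 0,
                          integral = c(0, 0, 0)) {
  if (dt <= 0) stop_gfsfan("dt must be > 0")
  an <- sqrt(sum(accel^2))
  err <- c(0, 0, 0)
  if (an > 0) {
    a_hat <- accel / an
    R <- quat_to_matrix(q)
    v_hat <- drop(crossprod(R, c(1, 0, 0)))   # predicted up direction, sensor frame
    err <- c(a_hat[2] * v_hat[3] - a_hat[3] * v_hat[2],
             a_hat[3] * v_hat[1] - a_hat[1] * v_hat[3],
             a_hat[1] * v_hat[2] - a_hat[2] * v_hat[1])
  }
  if (ki > 0) integral <- integral + err * dt
  omega <- gyro + kp * err + ki * integral
  ang <- sqrt(sum(omega^2)) * dt
  q_new <- if (ang > 0)
    quat_normalize(quat_multiply(q, quat_from_axis_angle(omega, ang))) else q
  if (ki > 0) attr(q_new, "integral") <- integral
  q_new
}

#' Tilt-only attitude from a gravity measurement
#'
#' Returns the yaw-free quaternion whose rotation maps the measured
#' (normalized) accelerometer direction to the reference up axis.
#'
#' @param accel accelerometer sample or mean, sensor frame.
#' @return Unit quaternion `R_sen^ref`.
#' @export
attitude_from_gravity <- function(accel) {
  a <- accel / sqrt(sum(accel^2))
  axis <- c(0, a[3], -a[2])                      # a x e_x
  s <- sqrt(sum(axis^2))
  ang <- atan2(s, a[1])
  if (s < 1e-12) {
    if (a[1] > 0) return(c(1, 0, 0, 0))
    return(c(0, 0, 1, 0))                        # 180 deg about y
  }
  quat_from_axis_angle(axis, ang)
}

#' Attitude quaternion traces for each IMU sensor
#'
#' Runs the Mahony filter over a recording's accelerometer/gyroscope
#' channels. The initial quaternion is the tilt-only attitude from the mean
#' standing-phase accelerometer (yaw set to zero).
#'
#' @param rec a `SignalRecording` with `acc` and `gyr` channels tagged by
#'   `sensor`.
#' @param sensors sensor ids (default: all IMU sensors in the recording).
#' @param kp,ki Mahony gains.
#' @return Named list of `n x 4` quaternion matrices, one per sensor;
#'   attribute `"rate"` holds the sampling rate.
#' @export
estimate_attitude <- function(rec, sensors = NULL, kp = 0.5, ki = 0) {
  stopifnot(inherits(rec, "SignalRecording"))
  sensors <- sensors %||%
    unique(rec$meta$sensor[rec$meta$modality == "acc" & !is.na(rec$meta$sensor)])
  out <- list()
  for (sens in sensors) {
    acc_nm <- sensor_triplet(rec, sens, "acc")
    gyr_nm <- sensor_triplet(rec, sens, "gyr")
    rate <- rec$meta$rate[match(acc_nm[1], rec$meta$name)]
    A <- do.call(cbind, rec$channels[acc_nm])
    G <- do.call(cbind, rec$channels[gyr_nm])
    n <- nrow(A)
    q0 <- if (!is.null(rec$standing_phase)) {
      sp <- rec$standing_phase
      idx <- (floor(sp[1] * rate) + 1):floor(sp[2] * rate)
      attitude_from_gravity(colMeans(A[idx, , drop = FALSE]))
    } else attitude_from_gravity(A[1, ])
    Q <- matrix(0, n, 4)
    q <- q0
    integral <- c(0, 0, 0)
    dt <- 1 / rate
    for (i in seq_len(n)) {
      q <- mahony_update(q, G[i, ], A[i, ], dt, kp, ki, integral)
      if (ki > 0) integral <- attr(q, "integral")
      Q[i, ] <- q
    }
    attr(Q, "rate") <- rate
    out[[sens]] <- Q
  }
  out
}

spherical_to_vec <- function(p) c(cos(p[2]) * cos(p[1]), cos(p[2]) * sin(p[1]), sin(p[2]))

#' Estimate a hinge axis from two synchronized gyroscope streams
#'
#' Self-calibrating hinge-axis identification: for segments joined by a
#' hinge, the angular-velocity components perpendicular to the axis have
#' equal norm in both sensor frames at every instant. The axes `(j1, j2)`
#' minimizing `sum((||g1 x j1|| - ||g2 x j2||)^2)` are found by
#' Gauss-Newton on spherical coordinates with four multi-starts. Requires
#' angular velocity of varying direction; pure rotation about the axis (or
#' rest) is non-identifiable.
#'
#' @param gyro1,gyro2 `n x 3` angular-velocity matrices, rad/s, sensor frames.
#' @param ref_axis sign reference: each axis is flipped so its dot product
#'   with `ref_axis` is positive (default `c(0, 1, 0)`).
#' @param max_iter,tol Gauss-Newton controls.
#' @return List with unit vectors `j1`, `j2` and the final `cost`.
#' @export
estimate_knee_axis <- function(gyro1, gyro2, ref_axis = c(0, 1, 0),
                               max_iter = 100, tol = 1e-8) {
  gyro1 <- as.matrix(gyro1); gyro2 <- as.matrix(gyro2)
  if (nrow(gyro1) != nrow(gyro2)) stop_gfsfan("gyro streams not synchronized")
  rms <- function(G) sqrt(mean(rowSums(G^2)))
  if (rms(gyro1) < 1e-3 || rms(gyro2) < 1e-3)
    stop_gfsfan("non-identifiable: insufficient gyroscope excitation")
  if (nrow(gyro1) > 3000) {                       # decimate long streams
    keep <- round(seq(1, nrow(gyro1), length.out = 3000))
    gyro1 <- gyro1[keep, , drop = FALSE]; gyro2 <- gyro2[keep, , drop = FALSE]
  }
  cross_norm <- function(G, j) {
    cx <- G[, 2] * j[3] - G[, 3] * j[2]
    cy <- G[, 3] * j[1] - G[, 1] * j[3]
    cz <- G[, 1] * j[2] - G[, 2] * j[1]
    sqrt(cx^2 + cy^2 + cz^2)
  }
  resid <- function(p) cross_norm(gyro1, spherical_to_vec(p[1:2])) -
    cross_norm(gyro2, spherical_to_vec(p[3:4]))
  starts <- list(c(0, 0), c(pi / 2, 0), c(0, pi / 2), c(pi / 4, atan(1 / sqrt(2))))
  best <- NULL
  for (s in starts) {
    p <- c(s, s)
    cost_prev <- Inf
    for (it in seq_len(max_iter)) {
      r <- resid(p)
      cost <- sum(r^2)
      J <- matrix(0, length(r), 4)
      h <- 1e-6
      for (k in 1:4) {
        ph <- p; ph[k] <- ph[k] + h
        J[, k] <- (resid(ph) - r) / h
      }
      step <- tryCatch(solve(crossprod(J) + 1e-10 * diag(4), crossprod(J, r)),
                       error = function(e) rep(0, 4))
      p <- p - drop(step)
      if (abs(cost_prev - cost) < tol * (1 + cost)) break
      cost_prev <- cost
    }
    cost <- sum(resid(p)^2)
    if (is.null(best) || cost < best$cost) best <- list(p = p, cost = cost)
  }
  j1 <- spherical_to_vec(best$p[1:2]); j2 <- spherical_to_vec(best$p[3:4])
  # identifiability: residual must be well below the perpendicular energy
  scale <- sum(cross_norm(gyro1, j1)^2) + sum(cross_norm(gyro2, j2)^2)
  if (scale < 1e-6)
    stop_gfsfan("non-identifiable: motion only about the joint axis")
  # the residual is invariant to independent sign flips of j1 and j2, but
  # joint angles are not: make the pair consistent (gyro projections onto
  # the two axes co-vary for a hinge), then orient the pair by ref_axis
  if (sum((gyro1 %*% j1) * (gyro2 %*% j2)) < 0) j2 <- -j2
  if (sum(j1 * ref_axis) < 0) { j1 <- -j1; j2 <- -j2 }
  list(j1 = j1, j2 = j2, cost = best$cost)
}

#' Sensor-to-segment calibration from standing/lying phases and hinge motion
#'
#' The segment x-axis (longitudinal, head-ward) of every sensor is the
#' normalized mean standing-phase accelerometer vector. For the low-back
#' segment the z-axis comes from the lying-phase gravity vector,
#' orthogonalized against x (Gram-Schmidt) and completed by `y = z x x`.
#' For a thigh/shank pair the y-axis (flexion axis) comes from hinge-axis
#' self-calibration on the motion-phase gyroscopes, orthogonalized via
#' `z = normalize(x x y_raw)`, `y = z x x`. The rotation
#' `R_seg^sen = [x, y, z]` is returned per segment.
#'
#' @param rec a `SignalRecording` with a standing phase.
#' @param roles named character vector mapping sensor id to role:
#'   `"thigh"`, `"shank"` or `"low_back"` (at most one thigh/shank pair).
#' @param motion_phase `c(start, end)` seconds of hinge motion used for axis
#'   self-calibration; default: everything after the standing phase.
#' @param ref_axis sign reference for the hinge axis, sensor frame.
#' @param static_sd "not static" threshold: maximum allowed per-axis
#'   standing-phase accelerometer standard deviation, m/s^2.
#' @return Named list of calibrations; each holds unit vectors `x`, `y`,
#'   `z`, the rotation `R` and the sensor id.
#' @export
calibrate_axes <- function(rec, roles, motion_phase = NULL,
                           ref_axis = c(0, 1, 0), static_sd = 1.0) {
  stopifnot(inherits(rec, "SignalRecording"))
  if (is.null(rec$standing_phase))
    stop_gfsfan("calibration requires a standing phase")
  sp <- rec$standing_phase
  x_axes <- list()
  for (sens in names(roles)) {
    acc_nm <- sensor_triplet(rec, sens, "acc")
    rate <- rec$meta$rate[match(acc_nm[1], rec$meta$name)]
    idx <- (floor(sp[1] * rate) + 1):floor(sp[2] * rate)
    A <- do.call(cbind, rec$channels[acc_nm])[idx, , drop = FALSE]
    if (max(apply(A, 2, sd)) > static_sd)
      stop_gfsfan("not static: standing-phase accelerometer variance above ",
                  "threshold for sensor '", sens, "'")
    m <- unname(colMeans(A))
    x_axes[[sens]] <- m / sqrt(sum(m^2))
  }
  out <- list()
  hinge <- names(roles)[roles %in% c("thigh", "shank")]
  if (length(hinge) == 2) {
    mp <- motion_phase %||% c(sp[2], recording_duration(rec))
    G <- lapply(hinge, function(sens) {
      gyr_nm <- sensor_triplet(rec, sens, "gyr")
      rate <- rec$meta$rate[match(gyr_nm[1], rec$meta$name)]
      idx <- (floor(mp[1] * rate) + 1):floor(mp[2] * rate)
      do.call(cbind, rec$channels[gyr_nm])[idx, , drop = FALSE]
    })
    axes <- estimate_knee_axis(G[[1]], G[[2]], ref_axis = ref_axis)
    js <- list(axes$j1, axes$j2)
    for (k in 1:2) {
      sens <- hinge[k]
      x <- x_axes[[sens]]; y_raw <- js[[k]]
      if (vector_angle_deg(x, y_raw) < 15 || vector_angle_deg(x, -y_raw) < 15)
        stop_gfsfan("degenerate calibration: hinge axis within 15 degrees ",
                    "of the longitudinal axis for sensor '", sens, "'")
      z <- c(x[2] * y_raw[3] - x[3] * y_raw[2],
             x[3] * y_raw[1] - x[1] * y_raw[3],
             x[1] * y_raw[2] - x[2] * y_raw[1])
      z <- z / sqrt(sum(z^2))
      y <- c(z[2] * x[3] - z[3] * x[2], z[3] * x[1] - z[1] * x[3],
             z[1] * x[2] - z[2] * x[1])
      out[[sens]] <- list(x = x, y = y, z = z, R = cbind(x = x, y = y, z = z),
                          sensor = sens, role = roles[[sens]])
    }
  } else if (length(hinge) == 1) {
    stop_gfsfan("hinge-axis calibration needs both a thigh and a shank sensor")
  }
  for (sens in names(roles)[roles == "low_back"]) {
    if (is.null(rec$lying_phase))
      stop_gfsfan("low-back calibration requires a lying phase")
    lp <- rec$lying_phase
    acc_nm <- sensor_triplet(rec, sens, "acc")
    rate <- rec$meta$rate[match(acc_nm[1], rec$meta$name)]
    idx <- (floor(lp[1] * rate) + 1):floor(lp[2] * rate)
    m <- unname(colMeans(do.call(cbind, rec$channels[acc_nm])[idx, , drop = FALSE]))
    z_raw <- m / sqrt(sum(m^2))
    x <- x_axes[[sens]]
    if (vector_angle_deg(x, z_raw) < 15 || vector_angle_deg(x, -z_raw) < 15)
      stop_gfsfan("degenerate calibration: standing and lying gravity axes ",
                  "within 15 degrees for sensor '", sens, "'")
    z <- z_raw - sum(z_raw * x) * x              # Gram-Schmidt
    z <- z / sqrt(sum(z^2))
    y <- c(z[2] * x[3] - z[3] * x[2], z[3] * x[1] - z[1] * x[3],
           z[1] * x[2] - z[2] * x[1])            # y = z x x
    out[[sens]] <- list(x = x, y = y, z = z, R = cbind(x = x, y = y, z = z),
                        sensor = sens, role = "low_back")
  }
  out
}

#' Express IMU channels in segment frames
#'
#' Each accelerometer/gyroscope sample `v` (sensor frame) is replaced by
#' `t(R_seg^sen) %*% v`, the same vector in the segment frame. Identity
#' calibrations reproduce the input; vector norms are preserved.
#'
#' @param rec a `SignalRecording`.
#' @param calibrations named list from [calibrate_axes()] (one per sensor).
#' @return The corrected `SignalRecording`.
#' @export
correct_imu <- function(rec, calibrations) {
  stopifnot(inherits(rec, "SignalRecording"))
  sensors <- unique(rec$meta$sensor[rec$meta$modality %in% c("acc", "gyr") &
                                      !is.na(rec$meta$sensor)])
  for (sens in sensors) {
    cal <- calibrations[[sens]]
    if (is.null(cal))
      stop_gfsfan("missing calibration for segment/sensor '", sens, "'")
    for (mod in c("acc", "gyr")) {
      nms <- tryCatch(sensor_triplet(rec, sens, mod), error = function(e) NULL)
      if (is.null(nms)) next
      V <- do.call(cbind, rec$channels[nms])
      W <- V %*% cal$R                            # = t(t(R) %*% t(V))
      for (j in 1:3) rec$channels[[nms[j]]] <- W[, j]
    }
  }
  rec
}

#' Joint angles from attitude traces and calibrations
#'
#' Composes each sensor attitude with its sensor-to-segment rotation
#' (`R_seg^ref = R_sen^ref %*% R_seg^sen`), zeroes all segment frames at the
#' standing snapshot (end of the standing phase), forms the relative
#' rotation between the two segments of each joint and reports the unsigned
#' angle between the proximal x-axis and the distal x-axis mapped into the
#' proximal frame, in degrees. Flexion and extension are not distinguished.
#'
#' @param rec a `SignalRecording` (used for the time base and standing phase).
#' @param calibrations named list from [calibrate_axes()].
#' @param traces attitude traces from [estimate_attitude()]; computed when
#'   `NULL`.
#' @param joints named list of `c(proximal_sensor, distal_sensor)` pairs;
#'   default: one joint between the two calibrated segments.
#' @param kp,ki Mahony gains used when `traces` is `NULL`.
#' @return Named list of data.frames `time`, `angle_deg`, `joint`.
#' @export
joint_angles <- function(rec, calibrations, traces = NULL, joints = NULL,
                         kp = 0.5, ki = 0) {
  stopifnot(inherits(rec, "SignalRecording"))
  if (is.null(traces))
    traces <- estimate_attitude(rec, sensors = names(calibrations),
                                kp = kp, ki = ki)
  for (sens in names(traces)) {
    bad <- abs(sqrt(rowSums(traces[[sens]]^2)) - 1) > 1e-6
    if (any(bad)) stop_gfsfan("non-unit quaternion in trace '", sens, "'")
  }
  if (is.null(joints)) {
    if (length(calibrations) < 2) stop_gfsfan("need two calibrated segments")
    joints <- list(joint = names(calibrations)[1:2])
  }
  n <- vapply(traces, nrow, 0L)
  if (length(unique(n)) != 1) stop_gfsfan("misaligned time bases across traces")
  n <- n[1]
  rate <- attr(traces[[1]], "rate")
  snap <- if (!is.null(rec$standing_phase))
    max(1L, floor(rec$standing_phase[2] * rate)) else 1L
  seg_R <- list()
  for (sens in names(calibrations)) {
    Q <- traces[[sens]]
    Rcal <- calibrations[[sens]]$R
    Rs <- lapply(seq_len(n), function(i) quat_to_matrix(Q[i, ]) %*% Rcal)
    R0 <- Rs[[snap]]
    seg_R[[sens]] <- lapply(Rs, function(R) crossprod(R0, R))
  }
  tvec <- (seq_len(n) - 1) / rate
  out <- list()
  for (jn in names(joints)) {
    pr <- joints[[jn]][1]; di <- joints[[jn]][2]
    ang <- vapply(seq_len(n), function(i) {
      Rrel <- crossprod(seg_R[[pr]][[i]], seg_R[[di]][[i]])
      acos(pmin(1, pmax(-1, Rrel[1, 1]))) * 180 / pi
    }, 0)
    out[[jn]] <- data.frame(time = tvec, angle_deg = ang, joint = jn)
  }
  out
}
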