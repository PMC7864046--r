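# Synthetic-data generators. These define the study conditions every other
# module is tested under: (a) class-structured multichannel signals whose
# windowed features separate a configurable number of activity classes,
# (b) rigid-body hinge-joint motion of two linked segments with known
# sensor-to-segment mount rotations and ground-truth joint angles, and
# (c) labelled feature tables with known informative features.

#' Specification for class-structured synthetic signals
#'
#' Each channel of each class is a sinusoid with class-dependent amplitude
#' and dominant frequency plus Gaussian noise. Label intervals tile the
#' recording; a leading quiet standing-like segment can be prepended.
#'
#' @param n_classes number of activity classes.
#' @param channels data.frame with columns `name`, `modality` (`"emg"`,
#'   `"acc"`, `"gyr"` or `"joint"`) and `rate` (Hz); optional `sensor`, `axis`.
#' @param class_params data.frame with columns `class` (1-based), `channel`,
#'   `amplitude`, `freq` (Hz), `noise_sd`. Defaults to amplitude `class`,
#'   frequency `2 * class` Hz and `noise_sd` 0.1 for every channel.
#' @param epoch_duration seconds per labelled epoch.
#' @param epochs_per_class epochs generated for each class.
#' @param standing_duration leading quiet segment, seconds (0 to disable).
#' @param seed integer seed; identical spec + seed reproduces identical output.
#' @return An object of class `SyntheticSignalSpec`.
#' @export
synthetic_signal_spec <- function(n_classes, channels, class_params = NULL,
                                  epoch_duration = 4, epochs_per_class = 4,
                                  standing_duration = 2, seed = 1) {
  if (n_classes < 1) stop_gfsfan("invalid spec: n_classes must be >= 1")
  if (epochs_per_class < 1) stop_gfsfan("invalid spec: epochs_per_class must be >= 1")
  if (epoch_duration <= 0) stop_gfsfan("invalid spec: non-positive epoch_duration")
  if (!is.data.frame(channels) || !all(c("name", "modality", "rate") %in% names(channels)))
    stop_gfsfan("invalid spec: channels needs columns name, modality, rate")
  if (any(channels$rate <= 0)) stop_gfsfan("invalid spec: non-positive rate")
  if (is.null(class_params)) {
    class_params <- expand.grid(class = seq_len(n_classes),
                                channel = channels$name,
                                stringsAsFactors = FALSE)
    class_params$amplitude <- class_params$class
    class_params$freq <- 2 * class_params$class
    class_params$noise_sd <- 0.1
  }
  structure(list(n_classes = n_classes, channels = channels,
                 class_params = class_params, epoch_duration = epoch_duration,
                 epochs_per_class = epochs_per_class,
                 standing_duration = standing_duration, seed = seed),
            class = "SyntheticSignalSpec")
}

#' Generate a class-structured multichannel recording
#'
#' Classes are interleaved (1, 2, ..., K, 1, 2, ...) after the optional quiet
#' standing segment. Sinusoid phase is continuous in global time, so a
#' noise-free single-class channel equals `amplitude * sin(2 * pi * f * t)`
#' exactly.
#'
#' @param spec a [synthetic_signal_spec()].
#' @return A `SignalRecording` with label intervals per epoch.
#' @export
generate_signals <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSignalSpec"))
  K <- spec$n_classes
  n_ep <- K * spec$epochs_per_class
  ep_class <- rep(seq_len(K), times = spec$epochs_per_class)
  ep_start <- spec$standing_duration + (seq_len(n_ep) - 1) * spec$epoch_duration
  labels <- data.frame(start = ep_start, end = ep_start + spec$epoch_duration,
                       activity = paste0("class", ep_class))
  total <- spec$standing_duration + n_ep * spec$epoch_duration
  meta <- spec$channels
  if (!"sensor" %in% names(meta)) meta$sensor <- NA_character_
  if (!"axis" %in% names(meta)) meta$axis <- NA_character_
  channels <- with_seed(spec$seed, {
    out <- list()
    for (i in seq_len(nrow(meta))) {
      nm <- meta$name[i]; rate <- meta$rate[i]
      n <- round(total * rate)
      t <- (seq_len(n) - 1) / rate
      x <- numeric(n)
      quiet_sd <- 0
      for (e in seq_len(n_ep)) {
        p <- spec$class_params[spec$class_params$class == ep_class[e] &
                                 spec$class_params$channel == nm, ]
        if (nrow(p) != 1)
          stop_gfsfan("invalid spec: class_params must have one row for class ",
                      ep_class[e], ", channel ", nm)
        idx <- which(t >= ep_start[e] - 1e-12 & t < ep_start[e] + spec$epoch_duration - 1e-12)
        x[idx] <- p$amplitude * sin(2 * pi * p$freq * t[idx])
        if (p$noise_sd > 0) x[idx] <- x[idx] + rnorm(length(idx), 0, p$noise_sd)
        quiet_sd <- max(quiet_sd, p$noise_sd / 10)
      }
      if (spec$standing_duration > 0 && quiet_sd > 0) {
        idx <- which(t < spec$standing_duration)
        x[idx] <- rnorm(length(idx), 0, quiet_sd)
      }
      out[[nm]] <- x
    }
    out
  })
  signal_recording(channels, meta, labels,
                   standing_phase = if (spec$standing_duration >= 1)
                     c(0, spec$standing_duration))
}

#' Specification for rigid-body hinge-joint motion
#'
#' Two linked segments (proximal, distal) share a hinge whose axis is fixed
#' in both segment frames. During the motion phase the hinge angle follows
#' `angle_trajectory`; a proximal-segment "wobble" (slow two-axis rotation)
#' can be superimposed so that both gyroscopes see angular velocity of
#' varying direction, which hinge-axis self-calibration requires. The angle
#' between the segments' longitudinal (x) axes always equals the hinge
#' trajectory. Accelerometers measure the gravity reaction only (+g along
#' the segment x-axis while standing); no linear-acceleration term is
#' simulated, isolating the calibration and attitude algorithms under test.
#'
#' @param joint_axis unit 3-vector, hinge axis in both segment frames
#'   (must be orthogonal to the x-axis; default `c(0, 1, 0)`).
#' @param angle_trajectory function mapping time-since-motion-start
#'   (seconds) to hinge angle in degrees; must start at 0.
#' @param mounts list of two 3x3 rotation matrices (`seg1`, `seg2`): the true
#'   sensor-to-segment rotations (columns = segment axes in sensor frame).
#' @param rate sampling rate, Hz.
#' @param standing_duration quiet standing phase before motion, seconds.
#' @param motion_duration motion phase duration, seconds.
#' @param gravity gravitational acceleration, m/s^2.
#' @param accel_noise_sd accelerometer noise sd, m/s^2.
#' @param gyro_noise_sd gyroscope noise sd, rad/s.
#' @param wobble `NULL` (auto: on iff the trajectory moves), `FALSE`, or a
#'   list with `amp_deg` (length 2) and `freq` (length 2, Hz).
#' @param seed integer seed for the noise streams.
#' @return An object of class `RigidBodySpec`.
#' @export
rigid_body_spec <- function(joint_axis = c(0, 1, 0),
                            angle_trajectory = function(t) 45 * sin(pi * t / 2)^2,
                            mounts = list(seg1 = diag(3), seg2 = diag(3)),
                            rate = 200, standing_duration = 5,
                            motion_duration = 10, gravity = 9.81,
                            accel_noise_sd = 0, gyro_noise_sd = 0,
                            wobble = NULL, seed = 1) {
  if (abs(sqrt(sum(joint_axis^2)) - 1) > 1e-6)
    stop_gfsfan("invalid spec: joint_axis must be a unit vector")
  for (nm in c("seg1", "seg2"))
    if (!is_rotation_matrix(mounts[[nm]]))
      stop_gfsfan("invalid spec: mount rotation '", nm,
                  "' is not orthonormal with det +1")
  if (rate <= 0 || standing_duration < 1 || motion_duration <= 0)
    stop_gfsfan("invalid spec: non-positive duration or rate")
  if (abs(angle_trajectory(0)) > 1e-9)
    stop_gfsfan("invalid spec: trajectory must start at 0 degrees")
  structure(list(joint_axis = joint_axis, angle_trajectory = angle_trajectory,
                 mounts = mounts, rate = rate,
                 standing_duration = standing_duration,
                 motion_duration = motion_duration, gravity = gravity,
                 accel_noise_sd = accel_noise_sd, gyro_noise_sd = gyro_noise_sd,
                 wobble = wobble, seed = seed),
            class = "RigidBodySpec")
}

default_wobble <- list(amp_deg = c(20, 12), freq = c(0.35, 0.27))

#' Simulate ideal IMU streams for two hinged segments
#'
#' @param spec a [rigid_body_spec()].
#' @return A list with `recording` (a `SignalRecording` with 12 channels:
#'   accelerometer and gyroscope x/y/z for sensors `seg1`, `seg2`),
#'   `truth` (data.frame `time`, `angle_deg`: the hinge angle),
#'   `mounts` (the true sensor-to-segment rotations) and `axis`.
#' @export
generate_rigid_body <- function(spec) {
  stopifnot(inherits(spec, "RigidBodySpec"))
  a <- spec$joint_axis
  g <- spec$gravity
  n_stand <- round(spec$standing_duration * spec$rate)
  n_mot <- round(spec$motion_duration * spec$rate)
  n <- n_stand + n_mot
  t <- (seq_len(n) - 1) / spec$rate
  tau <- pmax(0, t - spec$standing_duration)      # time since motion start
  moving <- t >= spec$standing_duration

  alpha_deg <- ifelse(moving, vapply(tau, spec$angle_trajectory, 0), 0)
  alpha <- alpha_deg * pi / 180
  h <- 1e-4
  alpha_dot <- ifelse(moving,
                      vapply(tau, function(x)
                        (spec$angle_trajectory(x + h) -
                           spec$angle_trajectory(max(0, x - h))) /
                          (h + min(x, h)), 0) * pi / 180, 0)

  wob <- spec$wobble
  if (is.null(wob)) {
    wob <- if (max(abs(alpha_deg)) > 1e-9) default_wobble else FALSE
  }
  if (isFALSE(wob)) {
    beta <- gamma <- beta_dot <- gamma_dot <- numeric(n)
  } else {
    w1 <- 2 * pi * wob$freq[1]; w2 <- 2 * pi * wob$freq[2]
    a1 <- wob$amp_deg[1] * pi / 180; a2 <- wob$amp_deg[2] * pi / 180
    beta <- ifelse(moving, a1 * sin(w1 * tau), 0)
    gamma <- ifelse(moving, a2 * sin(w2 * tau), 0)
    beta_dot <- ifelse(moving, a1 * w1 * cos(w1 * tau), 0)
    gamma_dot <- ifelse(moving, a2 * w2 * cos(w2 * tau), 0)
  }

  e_x <- c(1, 0, 0); e_z <- c(0, 0, 1)
  M1 <- spec$mounts$seg1; M2 <- spec$mounts$seg2
  acc1 <- gyr1 <- acc2 <- gyr2 <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    Rz <- rotation_about_axis(e_z, beta[i])
    Rx <- rotation_about_axis(e_x, gamma[i])
    W <- Rz %*% Rx                               # proximal attitude R_seg1^ref
    Ra <- rotation_about_axis(a, alpha[i])
    R1 <- W; R2 <- W %*% Ra                      # distal attitude R_seg2^ref
    # body-frame angular velocities (analytic)
    om1 <- drop(t(Rx) %*% (beta_dot[i] * e_z)) + gamma_dot[i] * e_x
    om2 <- drop(t(Ra) %*% om1) + alpha_dot[i] * a
    gyr1[i, ] <- drop(M1 %*% om1)
    gyr2[i, ] <- drop(M2 %*% om2)
    acc1[i, ] <- drop(M1 %*% t(R1) %*% (g * e_x))
    acc2[i, ] <- drop(M2 %*% t(R2) %*% (g * e_x))
  }
  if (spec$accel_noise_sd > 0 || spec$gyro_noise_sd > 0) {
    nz <- with_seed(spec$seed, list(
      a1 = matrix(rnorm(3 * n, 0, spec$accel_noise_sd), n, 3),
      a2 = matrix(rnorm(3 * n, 0, spec$accel_noise_sd), n, 3),
      g1 = matrix(rnorm(3 * n, 0, spec$gyro_noise_sd), n, 3),
      g2 = matrix(rnorm(3 * n, 0, spec$gyro_noise_sd), n, 3)))
    if (spec$accel_noise_sd > 0) { acc1 <- acc1 + nz$a1; acc2 <- acc2 + nz$a2 }
    if (spec$gyro_noise_sd > 0) { gyr1 <- gyr1 + nz$g1; gyr2 <- gyr2 + nz$g2 }
  }
  ax <- c("x", "y", "z")
  channels <- list()
  meta <- NULL
  for (seg in c("seg1", "seg2")) {
    A <- if (seg == "seg1") acc1 else acc2
    G <- if (seg == "seg1") gyr1 else gyr2
    for (j in 1:3) {
      channels[[paste0(seg, "_acc_", ax[j])]] <- A[, j]
      channels[[paste0(seg, "_gyr_", ax[j])]] <- G[, j]
    }
    meta <- rbind(meta, data.frame(
      name = c(paste0(seg, "_acc_", ax), paste0(seg, "_gyr_", ax)),
      modality = rep(c("acc", "gyr"), each = 3), rate = spec$rate,
      sensor = seg, axis = rep(ax, 2), stringsAsFactors = FALSE))
  }
  labels <- data.frame(
    start = c(0, spec$standing_duration),
    end = c(spec$standing_duration, spec$standing_duration + spec$motion_duration),
    activity = c("standing", "motion"))
  rec <- signal_recording(channels, meta, labels,
                          standing_phase = c(0, spec$standing_duration))
  list(recording = rec,
       truth = data.frame(time = t, angle_deg = abs(alpha_deg)),
       mounts = spec$mounts, axis = a)
}

#' Specification for a labelled synthetic feature table
#'
#' Informative features are class-mean-shifted Gaussians; redundant features
#' are noisy copies of informative ones (noise sd = `noise_sd / 10`); the
#' remaining features are class-independent Gaussian noise.
#'
#' @param n_features total number of features.
#' @param n_informative number of class-informative features.
#' @param samples_per_class integer vector of per-class sample counts
#'   (possibly imbalanced); its length sets the number of classes.
#' @param class_means optional `n_informative x n_classes` matrix of class
#'   means. Default: means staggered by `mean_gap * noise_sd` so every class
#'   pair differs on every informative feature.
#' @param mean_gap class-mean separation in units of `noise_sd` (default 3).
#' @param noise_sd within-class standard deviation.
#' @param n_redundant number of redundant (near-duplicate) features.
#' @param seed integer seed.
#' @return An object of class `SyntheticFeatureSpec`.
#' @export
synthetic_feature_spec <- function(n_features, n_informative, samples_per_class,
                                   class_means = NULL, mean_gap = 3,
                                   noise_sd = 1, n_redundant = 0, seed = 1) {
  K <- length(samples_per_class)
  if (K < 1 || any(samples_per_class < 1))
    stop_gfsfan("invalid spec: samples_per_class must be positive counts")
  if (n_informative + n_redundant > n_features)
    stop_gfsfan("invalid spec: n_informative + n_redundant > n_features")
  if (is.null(class_means) && n_informative > 0) {
    # complementary one-vs-rest coding: informative feature f elevates the
    # mean of class ((f-1) mod K) + 1 only, so each feature carries
    # information no other (non-duplicate) feature provides and subsets
    # smaller than min(n_informative, K) cannot separate every class
    class_means <- outer(seq_len(n_informative), seq_len(K),
                         function(f, c) mean_gap * noise_sd *
                           ((c - 1) == (f - 1) %% K))
  }
  if (n_informative > 0) {
    if (!all(dim(class_means) == c(n_informative, K)))
      stop_gfsfan("invalid spec: class_means must be n_informative x n_classes")
    same <- apply(class_means, 1, function(m) length(unique(round(m, 12))) < 2)
    if (any(same))
      stop_gfsfan("invalid spec: class_means must differ across classes")
  }
  structure(list(n_features = n_features, n_informative = n_informative,
                 n_redundant = n_redundant, samples_per_class = samples_per_class,
                 class_means = class_means, noise_sd = noise_sd, seed = seed),
            class = "SyntheticFeatureSpec")
}

#' Generate a labelled feature table with known informative features
#'
#' @param spec a [synthetic_feature_spec()].
#' @return A `FeatureTable`; attribute `informative` holds the indices of
#'   the informative features, `redundant` those of the redundant copies.
#' @export
generate_feature_table <- function(spec) {
  stopifnot(inherits(spec, "SyntheticFeatureSpec"))
  K <- length(spec$samples_per_class)
  n <- sum(spec$samples_per_class)
  y <- rep(seq_len(K), times = spec$samples_per_class)
  p <- spec$n_features
  ni <- spec$n_informative; nr <- spec$n_redundant
  x <- with_seed(spec$seed, {
    x <- matrix(rnorm(n * p, 0, spec$noise_sd), n, p)
    if (ni > 0)
      for (f in seq_len(ni)) x[, f] <- x[, f] + spec$class_means[f, y]
    if (nr > 0)
      for (r in seq_len(nr)) {
        src <- (r - 1) %% ni + 1
        x[, ni + r] <- x[, src] + rnorm(n, 0, spec$noise_sd / 10)
      }
    x
  })
  colnames(x) <- sprintf("F%03d", seq_len(p))
  info <- data.frame(name = colnames(x), modality = NA_character_,
                     sensor = NA_character_, channel = NA_character_,
                     feature = c(rep("informative", ni), rep("redundant", nr),
                                 rep("noise", p - ni - nr)),
                     component = NA_integer_, stringsAsFactors = FALSE)
  ft <- feature_table(x, paste0("class", y), info = info)
  attr(ft, "informative") <- seq_len(ni)
  attr(ft, "redundant") <- if (nr > 0) ni + seq_len(nr) else integer(0)
  ft
}
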