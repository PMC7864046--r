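# Shared fixtures, built in code.

random_rotation <- function() quat_to_matrix(quat_normalize(rnorm(4)))

# one-channel recording with a single labelled span
flat_recording <- function(duration = 10.4, rate = 200, label = "walk") {
  n <- round(duration * rate)
  signal_recording(
    channels = list(c1 = sin(2 * pi * 3 * (seq_len(n) - 1) / rate)),
    meta = data.frame(name = "c1", modality = "joint", rate = rate,
                      sensor = NA_character_, axis = NA_character_),
    labels = data.frame(start = 0, end = duration, activity = label))
}

small_emg_spec <- function(seed = 9, amplitudes = c(1, 3)) {
  synthetic_signal_spec(
    n_classes = 2,
    channels = data.frame(name = "e1", modality = "emg", rate = 500),
    class_params = data.frame(class = 1:2, channel = "e1",
                              amplitude = amplitudes, freq = 5,
                              noise_sd = 0.1),
    epoch_duration = 4, epochs_per_class = 4, standing_duration = 2,
    seed = seed)
}

balanced_table <- function(n_features = 10, n_informative = 3,
                           per_class = 40, classes = 3, seed = 4, ...) {
  generate_feature_table(synthetic_feature_spec(
    n_features, n_informative, samples_per_class = rep(per_class, classes),
    seed = seed, ...))
}

hinge_sim <- function(peak = 45, mounts = NULL, seed = 1, accel_noise = 0,
                      gyro_noise = 0) {
  mounts <- mounts %||% list(seg1 = diag(3), seg2 = diag(3))
  generate_rigid_body(rigid_body_spec(
    angle_trajectory = function(t) peak * sin(pi * t / 2)^2,
    mounts = mounts, standing_duration = 5, motion_duration = 10,
    accel_noise_sd = accel_noise, gyro_noise_sd = gyro_noise, seed = seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
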