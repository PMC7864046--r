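test_that("Mahony filter is at equilibrium when gravity agrees", {
  q <- quat_from_axis_angle(c(0, 0, 1), 0.4)
  a <- drop(crossprod(quat_to_matrix(q), c(9.81, 0, 0)))
  q2 <- mahony_update(q, c(0, 0, 0), a, 1 / 200, kp = 0.5)
  expect_equal(q2, q, tolerance = 1e-12)
})

test_that("constant-rate gyro integration matches the axis-angle closed form", {
  for (w in list(c(0, 0, 1), c(0.3, -0.2, 0.5))) {
    q <- c(1, 0, 0, 0)
    dt <- 1 / 1000
    for (i in 1:1000) q <- mahony_update(q, w, c(0, 0, 0), dt, kp = 0.5)
    ang <- sqrt(sum(w^2))                   # |w| * 1 s
    expect_equal(rotation_distance_deg(quat_to_matrix(q),
                                       rotation_about_axis(w, ang)),
                 0, tolerance = 1e-4)
  }
})

test_that("accelerometer correction pulls a tilted estimate to gravity", {
  q <- quat_from_axis_angle(c(0, 1, 0), 30 * pi / 180)
  for (i in 1:2000) q <- mahony_update(q, c(0, 0, 0), c(9.81, 0, 0), 1 / 200)
  expect_lt(rotation_distance_deg(quat_to_matrix(q), diag(3)), 0.5)
})

test_that("zero-norm accelerometer samples fall back to gyro integration", {
  q <- quat_from_axis_angle(c(1, 0, 0), 0.2)
  q2 <- mahony_update(q, c(0, 0, 0), c(0, 0, 0), 0.005)
  expect_equal(q2, q)
  expect_error(mahony_update(q, c(0, 0, 0), c(9.81, 0, 0), 0), "dt")
})

test_that("identity-mount standing calibration returns identity axes", {
  sim <- hinge_sim(peak = 40)
  cal <- calibrate_axes(sim$recording, c(seg1 = "thigh", seg2 = "shank"))
  expect_equal(cal$seg1$x, c(1, 0, 0), tolerance = 1e-9)
  expect_lt(rotation_distance_deg(cal$seg1$R, diag(3)), 0.1)
  # orthonormality postcondition
  for (cl in cal) {
    expect_lt(max(abs(crossprod(cl$R) - diag(3))), 1e-9)
    expect_equal(det(cl$R), 1, tolerance = 1e-9)
  }
})

test_that("random mount rotations are recovered within 1 degree up to a
           consistent hinge-axis flip", {
  # the hinge axis direction (medial vs lateral) is unobservable from the
  # streams alone; estimation may flip y and z of BOTH segments together
  # (the 180-degree flip about x), which leaves every joint angle unchanged
  D <- diag(c(1, -1, -1))
  set.seed(42)
  for (rep in 1:3) {
    M1 <- random_rotation(); M2 <- random_rotation()
    sim <- hinge_sim(peak = 60, mounts = list(seg1 = M1, seg2 = M2))
    cal <- calibrate_axes(sim$recording, c(seg1 = "thigh", seg2 = "shank"))
    d1 <- rotation_distance_deg(cal$seg1$R, M1)
    d1f <- rotation_distance_deg(cal$seg1$R, M1 %*% D)
    d2 <- rotation_distance_deg(cal$seg2$R, M2)
    d2f <- rotation_distance_deg(cal$seg2$R, M2 %*% D)
    expect_lt(min(d1, d1f), 1)
    expect_lt(min(d2, d2f), 1)
    expect_equal(d1 < d1f, d2 < d2f)     # flips are consistent across the pair
  }
})

test_that("moving standing phases are rejected as not static", {
  sim <- hinge_sim(peak = 40)
  rec <- sim$recording
  rec$channels$seg1_acc_y <- rec$channels$seg1_acc_y +
    5 * sin(seq_along(rec$channels$seg1_acc_y) / 10)
  expect_error(calibrate_axes(rec, c(seg1 = "thigh", seg2 = "shank")),
               "not static")
})

test_that("hinge-axis self-calibration recovers known axes", {
  sim <- hinge_sim(peak = 50)
  g1 <- do.call(cbind, sim$recording$channels[paste0("seg1_gyr_",
                                                     c("x", "y", "z"))])
  g2 <- do.call(cbind, sim$recording$channels[paste0("seg2_gyr_",
                                                     c("x", "y", "z"))])
  mot <- 1001:3000
  ax <- estimate_knee_axis(g1[mot, ], g2[mot, ])
  expect_lt(vector_angle_deg(ax$j1, c(0, 1, 0)), 0.5)
  expect_lt(vector_angle_deg(ax$j2, c(0, 1, 0)), 0.5)
  # with random mounts the recovered axes are the mount-rotated truth
  set.seed(8)
  M1 <- random_rotation(); M2 <- random_rotation()
  sim2 <- hinge_sim(peak = 50, mounts = list(seg1 = M1, seg2 = M2))
  h1 <- do.call(cbind, sim2$recording$channels[paste0("seg1_gyr_",
                                                      c("x", "y", "z"))])
  h2 <- do.call(cbind, sim2$recording$channels[paste0("seg2_gyr_",
                                                      c("x", "y", "z"))])
  ax2 <- estimate_knee_axis(h1[mot, ], h2[mot, ])
  t1 <- drop(M1 %*% c(0, 1, 0)); t2 <- drop(M2 %*% c(0, 1, 0))
  expect_lt(min(vector_angle_deg(ax2$j1, t1), vector_angle_deg(ax2$j1, -t1)), 1)
  expect_lt(min(vector_angle_deg(ax2$j2, t2), vector_angle_deg(ax2$j2, -t2)), 1)
})

test_that("zero-motion gyro input is non-identifiable", {
  z <- matrix(0, 500, 3)
  expect_error(estimate_knee_axis(z, z), "non-identifiable")
})

test_that("correct_imu is the identity under identity calibration and an isometry", {
  sim <- hinge_sim(peak = 30)
  id_cal <- list(seg1 = list(R = diag(3)), seg2 = list(R = diag(3)))
  expect_equal(correct_imu(sim$recording, id_cal)$channels,
               sim$recording$channels)
  M <- rotation_about_axis(c(1, 0, 0), pi / 2)
  cal <- list(seg1 = list(R = M), seg2 = list(R = diag(3)))
  out <- correct_imu(sim$recording, cal)
  a_in <- do.call(cbind, sim$recording$channels[paste0("seg1_acc_",
                                                       c("x", "y", "z"))])
  a_out <- do.call(cbind, out$channels[paste0("seg1_acc_", c("x", "y", "z"))])
  expect_equal(rowSums(a_in^2), rowSums(a_out^2), tolerance = 1e-12)
  expect_error(correct_imu(sim$recording, cal[1]), "seg2")
})

test_that("a 90-degree mount is unwound onto the segment x-axis", {
  # gravity measured along sensor y when the mount rotates segment x to
  # sensor y: R_seg^sen = rotation by +90 deg about z
  M <- rotation_about_axis(c(0, 0, 1), pi / 2)
  sim <- generate_rigid_body(rigid_body_spec(
    angle_trajectory = function(t) 0, mounts = list(seg1 = M, seg2 = diag(3)),
    standing_duration = 2, motion_duration = 1))
  expect_equal(sim$recording$channels$seg1_acc_y[10], 9.81, tolerance = 1e-9)
  out <- correct_imu(sim$recording, list(seg1 = list(R = M),
                                         seg2 = list(R = diag(3))))
  expect_equal(out$channels$seg1_acc_x[10], 9.81, tolerance = 1e-9)
  expect_equal(out$channels$seg1_acc_y[10], 0, tolerance = 1e-9)
})

test_that("joint angles are zero at standing and recover the simulated peak", {
  sim <- hinge_sim(peak = 45)
  cal <- calibrate_axes(sim$recording, c(seg1 = "thigh", seg2 = "shank"))
  ja <- joint_angles(sim$recording, cal)$joint
  expect_lt(max(abs(ja$angle_deg[ja$time < 4.9])), 0.2)
  expect_equal(max(ja$angle_deg), 45, tolerance = 0.5)
})

test_that("perpendicular axes give exactly 90 degrees", {
  expect_equal(vector_angle_deg(c(1, 0, 0), c(0, 1, 0)), 90)
  expect_equal(vector_angle_deg(c(1, 0, 0), c(-1, 0, 0)), 180)
})

test_that("non-unit quaternion traces are rejected", {
  sim <- hinge_sim(peak = 30)
  cal <- calibrate_axes(sim$recording, c(seg1 = "thigh", seg2 = "shank"))
  tr <- estimate_attitude(sim$recording)
  tr$seg1[5, ] <- tr$seg1[5, ] * 2
  expect_error(joint_angles(sim$recording, cal, traces = tr), "non-unit")
})

test_that("noise-free end-to-end recovery stays within a degree", {
  set.seed(11)
  for (rep in 1:3) {
    peak <- runif(1, 20, 90)
    sim <- hinge_sim(peak = peak,
                     mounts = list(seg1 = random_rotation(),
                                   seg2 = random_rotation()))
    cal <- calibrate_axes(sim$recording, c(seg1 = "thigh", seg2 = "shank"))
    ja <- joint_angles(sim$recording, cal)$joint
    expect_lt(abs(max(ja$angle_deg) - peak), 1)
  }
})

test_that("low-back calibration from standing plus lying phases", {
  # static body: standing 0-5 s (gravity on segment x), lying 5-10 s
  # (gravity on segment z); known mount rotation
  set.seed(13)
  M <- random_rotation()
  rate <- 200; n <- 10 * rate
  g_seg <- rbind(matrix(rep(c(9.81, 0, 0), each = n / 2), n / 2, 3),
                 matrix(rep(c(0, 0, 9.81), each = n / 2), n / 2, 3))
  A <- g_seg %*% t(M)                       # v_sen = M v_seg
  channels <- list()
  for (j in 1:3) {
    channels[[paste0("lb_acc_", c("x", "y", "z")[j])]] <- A[, j]
    channels[[paste0("lb_gyr_", c("x", "y", "z")[j])]] <- numeric(n)
  }
  rec <- signal_recording(
    channels,
    meta = data.frame(name = names(channels),
                      modality = rep(c("acc", "gyr"), 3), rate = rate,
                      sensor = "lb", axis = rep(c("x", "y", "z"), each = 2)),
    standing_phase = c(0, 5), lying_phase = c(5.1, 9.9))
  cal <- calibrate_axes(rec, c(lb = "low_back"))
  expect_lt(rotation_distance_deg(cal$lb$R, M), 0.1)
  rec$lying_phase <- NULL
  expect_error(calibrate_axes(rec, c(lb = "low_back")), "lying")
})
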