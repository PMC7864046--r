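# The naive reference implementations live in helper-oracles.R.

test_that("time-domain features match the naive reference on random windows", {
  set.seed(101)
  for (r in 1:100) {
    x <- rnorm(64, sd = runif(1, 0.1, 5)) + runif(1, -1, 1)
    d <- 0.01 * sqrt(mean(x^2))
    got <- compute_td(x)
    want <- naive_td(x, d, d, d)
    expect_equal(got[names(want)], want, tolerance = 1e-10)
    expect_equal(unname(got[paste0("ARC", 1:4)]), naive_burg(x, 4),
                 tolerance = 1e-10)
  }
})

test_that("frequency-domain features match the direct-DFT reference", {
  set.seed(202)
  for (r in 1:20) {
    x <- rnorm(64)
    expect_equal(compute_fd(x, 200), naive_fd(x, 200), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("hand-computable time-domain examples", {
  # WL, P2P, MV on [1, 3, 2] (padded to the minimum window length by
  # checking the formulas directly on short vectors through the reference)
  x <- c(1, 3, 2)
  expect_equal(sum(abs(diff(x))), 3)
  expect_equal(max(x) - min(x), 2)
  expect_equal(mean(x), 2)
  v <- compute_td(c(1, 3, 2, 1, 3, 2, 1, 3))
  expect_equal(unname(v["WL"]), sum(abs(diff(c(1, 3, 2, 1, 3, 2, 1, 3)))))
  expect_equal(unname(v["P2P"]), 2)
  # VAR and SD on [0, 2]: mean-centered, N - 1 denominator
  w <- compute_td(rep(c(0, 2), 4))
  expect_equal(unname(w["VAR"]), var(rep(c(0, 2), 4)))
  expect_equal(unname(w["SD"]), sqrt(unname(w["VAR"])))
  # ZC rule on an alternating window with a gate it clears
  z <- compute_td(rep(c(1, -1), 4), params = list(delta_z = 0.5))
  expect_equal(unname(z["ZC"]), 7)        # all 7 adjacent sign flips, gap 2
  z3 <- rep(c(1, -1), 4)
  expect_equal(sum(z3[-8] * z3[-1] < 0 & abs(diff(z3)) > 0.5), 7)
})

test_that("tri-axial sensor features on a constant window", {
  X3 <- matrix(rep(c(1, -2, 3), each = 16), ncol = 3)
  sv <- gfsfan:::sensor_features(X3, "acc")
  expect_equal(unname(sv["Jerk"]), 0)
  expect_equal(unname(sv["SMA"]), mean(abs(X3[, 1]) + abs(X3[, 2]) +
                                         abs(X3[, 3])))
  expect_equal(unname(sv[c("CCxy", "CCxz", "CCyz")]), c(0, 0, 0))
  # gyr layout has no Jerk
  expect_false("Jerk" %in% names(gfsfan:::sensor_features(X3, "gyr")))
})

test_that("spectral features on constructed tones", {
  rate <- 200; N <- 200
  t <- (0:(N - 1)) / rate
  # two equal lines at 10 and 20 Hz -> MPF is their midpoint
  v <- compute_fd(sin(2 * pi * 10 * t) + sin(2 * pi * 20 * t), rate)
  expect_equal(unname(v["MPF"]), 15, tolerance = 1e-9)
  # a pure 5 Hz tone concentrates all power in one bin
  u <- compute_fd(sin(2 * pi * 5 * t), rate)
  expect_equal(unname(u[c("MDF", "F25", "F75")]), c(5, 5, 5))
  expect_equal(unname(u["LVD1"]), N / 2, tolerance = 1e-9)  # line magnitude
  # impulse -> flat spectrum -> maximum entropy log(n)
  imp <- c(1, rep(0, N - 1))
  expect_equal(unname(compute_fd(imp, rate)["Entropy"]), log(N / 2),
               tolerance = 1e-12)
  # all-zero window flagged
  z <- compute_fd(rep(0, 32), rate)
  expect_equal(unname(z["MPF"]), 0)
  expect_equal(attr(z, "flags"), "FD_zero_window")
})

test_that("sym4 wavelet decomposition reproduces frozen oracle energies", {
  # oracle values computed with an independent reference implementation of
  # the same transform (symmetric extension), frozen here
  x <- sin(2 * pi * (0:207) * 7 / 208) + 0.25 * cos(2 * pi * (0:207) * 31 / 208)
  e <- wavelet_energies(x)
  expect_equal(unname(e), c(3.5505424408223436, 3.111295652015488,
                            0.19081938092783068, 0.09315273390157854,
                            0.002605353372865263), tolerance = 1e-12)
  w <- wavedec_sym4(x, 4)
  expect_equal(vapply(c(list(w$A), rev(w$D)), length, 0L),
               c(19L, 19L, 32L, 57L, 107L))
})

test_that("periodized transform conserves energy (Parseval)", {
  set.seed(33)
  for (r in 1:10) {
    x <- rnorm(256)
    w <- wavedec_sym4(x, 4, mode = "periodization")
    tot <- sum(w$A^2) + sum(vapply(w$D, function(d) sum(d^2), 0))
    expect_equal(tot, sum(x^2), tolerance = 1e-10)
  }
})

test_that("wavelet edge cases behave", {
  expect_equal(unname(wavelet_energies(rep(0, 64))), rep(0, 5))
  # an impulse is a broadband event: the finest detail dominates the
  # coarse details
  imp <- c(rep(0, 100), 1, rep(0, 107))
  e <- wavelet_energies(imp)
  expect_gt(e[["EWC_D1"]], e[["EWC_D4"]])
  expect_error(wavedec_sym4(rnorm(16), 4), "too short")
})

test_that("feature enumeration matches the closed-form arity sums", {
  inv <- study_sensor_inventory()
  ef <- enumerate_features(inv)
  per_channel <- c(emg = 33, acc = 30, gyr = 33, joint = 25)
  closed <- sum(per_channel[inv$modality]) +
    5 * length(unique(inv$sensor[inv$modality == "acc" & !is.na(inv$sensor)])) +
    4 * length(unique(inv$sensor[inv$modality == "gyr" & !is.na(inv$sensor)]))
  expect_equal(nrow(ef), closed)
  # any user inventory: drop a sensor, counts follow
  inv2 <- inv[!(inv$sensor %in% "LS"), ]
  expect_equal(nrow(enumerate_features(inv2)),
               closed - 3 * 30 - 3 * 33 - 5 - 4)
  expect_error(gfsfan:::modality_features("ecg"), "unknown modality")
})

test_that("amplitude scaling covariance and invariance", {
  set.seed(44)
  x <- rnorm(64)
  a <- compute_td(x); b <- compute_td(3 * x)
  for (f in c("MV", "SD", "RMS", "MAV", "WL", "P2P"))
    expect_equal(unname(b[f]), 3 * unname(a[f]), tolerance = 1e-10)
  for (f in c("SKE", "KUR"))
    expect_equal(unname(b[f]), unname(a[f]), tolerance = 1e-10)
  X3 <- matrix(rnorm(48), ncol = 3)
  expect_equal(gfsfan:::sensor_features(3 * X3, "gyr")[c("CCxy", "CCxz", "CCyz")],
               gfsfan:::sensor_features(X3, "gyr")[c("CCxy", "CCxz", "CCyz")],
               tolerance = 1e-12)
})

test_that("min-max normalization maps, flags and extrapolates correctly", {
  ft <- feature_table(cbind(a = c(2, 4, 6), b = c(5, 5, 5)),
                      c("x", "y", "x"))
  nf <- normalize_minmax(ft)
  expect_equal(unname(nf$x[, "a"]), c(0, 0.5, 1))
  expect_equal(unname(nf$x[, "b"]), c(0, 0, 0))
  expect_true(nf$norm$constant[["b"]])
  # stored parameters applied to new data: no clipping
  new <- feature_table(cbind(a = 8, b = 5), "x")
  out <- normalize_minmax(new, params = nf$norm)
  expect_equal(unname(out$x[1, "a"]), 1.5)
})

test_that("constant windows are flagged, not fatal", {
  v <- compute_td(rep(2, 32))
  expect_equal(unname(v[c("SKE", "KUR")]), c(0, 0))
  expect_true(all(c("SKE_constant", "KUR_constant") %in% attr(v, "flags")))
})
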