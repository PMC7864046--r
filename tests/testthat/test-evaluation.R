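test_that("F-measure matches hand-computed confusion matrices", {
  cm <- matrix(c(3, 1, 1, 3), 2, 2, byrow = TRUE)
  r <- f_measure(cm)
  expect_equal(unname(r$fm), c(0.75, 0.75))
  expect_equal(r$fm_all, 0.75)
  expect_equal(r$fm_min, 0.75)
  expect_equal(unname(r$precision), c(0.75, 0.75))
  expect_equal(unname(r$recall), c(0.75, 0.75))
  # diagonal matrix: perfect
  d <- f_measure(diag(c(5, 7, 9)))
  expect_equal(unname(d$fm), c(1, 1, 1))
  # a class never predicted and never present -> FM 0, flagged
  z <- f_measure(matrix(c(4, 0, 0, 0), 2, 2))
  expect_equal(unname(z$fm[2]), 0)
  expect_true(2 %in% z$flagged)
  expect_error(f_measure(matrix(0, 2, 2)), "no predictions")
})

test_that("F-measure is invariant under simultaneous relabeling", {
  set.seed(3)
  cm <- matrix(rpois(9, 5), 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  p <- c(3, 1, 2)
  r1 <- f_measure(cm)
  r2 <- f_measure(cm[p, p])
  expect_equal(sort(r1$fm), sort(r2$fm))
  expect_equal(r1$fm_all, r2$fm_all)
})

test_that("native LDA and naive Bayes agree with library implementations", {
  set.seed(17)
  ft <- balanced_table(6, 3, per_class = 50, classes = 3, seed = 17)
  tr <- sample(nrow(ft$x), 100)
  xtr <- ft$x[tr, ]; ytr <- droplevels(ft$labels[tr])
  xte <- ft$x[-tr, ]
  lda_native <- make_classifier("lda")
  p1 <- lda_native$predict(lda_native$fit(xtr, ytr), xte)
  p2 <- predict(MASS::lda(xtr, grouping = ytr),
                as.data.frame(xte))$class
  expect_gt(mean(p1 == p2), 0.98)
  nb_native <- make_classifier("nb")
  p3 <- nb_native$predict(nb_native$fit(xtr, ytr), xte)
  p4 <- predict(e1071::naiveBayes(as.data.frame(xtr), ytr),
                as.data.frame(xte))
  expect_gt(mean(p3 == p4), 0.98)
})

test_that("a perfectly separated table scores FM = 1 with 1-NN", {
  ft <- balanced_table(5, 3, per_class = 30, seed = 23, mean_gap = 12,
                       noise_sd = 0.2)
  r <- evaluate_subset(ft, classifier = "knn", seed = 2)
  expect_equal(r$fm_all, 1)
})

test_that("label permutation drives performance to chance", {
  set.seed(99)
  ft <- balanced_table(6, 3, per_class = 60, classes = 2, seed = 31)
  perm <- feature_table(ft$x, sample(as.character(ft$labels)))
  fms <- vapply(1:5, function(s)
    evaluate_subset(perm, classifier = "lda", seed = s)$fm_all, 0)
  expect_lt(abs(mean(fms) - 0.5), 0.1)
})

test_that("evaluation is deterministic and order-invariant in features", {
  ft <- balanced_table(8, 3, per_class = 30, seed = 41)
  r1 <- evaluate_subset(ft, classifier = "rf", seed = 7)
  r2 <- evaluate_subset(ft, classifier = "rf", seed = 7)
  expect_identical(r1$confusion, r2$confusion)
  perm <- sample(ncol(ft$x))
  ftp <- ft_subset(ft, features = perm)
  r3 <- evaluate_subset(ftp, classifier = "lda", seed = 7)
  r4 <- evaluate_subset(ft, classifier = "lda", seed = 7)
  expect_equal(r3$fm_all, r4$fm_all)
})

test_that("all six classifiers run under the uniform contract", {
  ft <- balanced_table(6, 3, per_class = 25, seed = 13, mean_gap = 4)
  for (cl in c("centroid", "knn", "lda", "nb", "rf", "svm")) {
    r <- evaluate_subset(ft, classifier = cl, folds = 5, seed = 3)
    expect_gt(r$fm_all, 0.8)
  }
  expect_error(make_classifier("mlp"), "unknown classifier")
})

test_that("stratified folds keep every class in every fold", {
  y <- factor(rep(c("a", "b", "c"), c(40, 25, 15)))
  f <- stratified_folds(y, 10, seed = 5)
  for (k in 1:10) expect_equal(nlevels(droplevels(y[f != k])), 3)
})

test_that("the sensor-combination sweep respects modality provenance", {
  rec <- generate_signals(synthetic_signal_spec(
    2,
    data.frame(name = c("e1", paste("s1", rep(c("acc", "gyr"), each = 3),
                                    c("x", "y", "z"), sep = "_")),
               modality = c("emg", rep(c("acc", "gyr"), each = 3)),
               rate = c(1000, rep(200, 6)),
               sensor = c(NA, rep("s1", 6)),
               axis = c(NA, rep(c("x", "y", "z"), 2))),
    epoch_duration = 3, epochs_per_class = 2, standing_duration = 0,
    seed = 6))
  ft <- extract_features(segment(rec, 800, 0.5))
  grid <- sensor_combination_sweep(ft, classifiers = "centroid", folds = 4,
                                   seed = 2)
  fn <- setNames(grid$fn, grid$combination)
  expect_equal(unname(fn["IMU"]), unname(fn["ACC"] + fn["GYR"]))
  expect_equal(unname(fn["sEMG+IMU"]), unname(fn["sEMG"] + fn["IMU"]))
  # selector = NULL uses the full column set of each combination
  sub <- ft_subset(ft, features = which(ft$info$modality == "emg"))
  direct <- evaluate_subset(sub, classifier = "centroid", folds = 4, seed = 2)
  expect_equal(grid$fm[grid$combination == "sEMG"], direct$fm_all)
  expect_error(sensor_combination_sweep(
    ft, combinations = list(bad = list(modality = "mag"))), "no features")
})
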