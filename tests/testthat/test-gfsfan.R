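test_that("selection probabilities follow the arithmetic sequence", {
  expect_equal(selection_probabilities(1:3), c(0.8, 0.6, 0.4))
  expect_equal(selection_probabilities(1:2), c(0.8, 0.4))
  expect_equal(selection_probabilities(1L), 0.8)
  sp <- selection_probabilities(1:50)
  expect_true(all(sp >= 0.4 & sp <= 0.8))
  expect_true(all(diff(sp) < 0))          # strictly decreasing in rank
  # probabilities are indexed by feature, not rank: ranking[1] names the
  # top-FI feature, which gets P1
  expect_equal(selection_probabilities(c(3L, 1L, 2L)), c(0.6, 0.4, 0.8))
})

test_that("weighted initialization activates exactly ninit bits", {
  sp <- selection_probabilities(1:20)
  m <- init_individual(sp, 7, seed = 3)
  expect_equal(sum(m), 7)
  expect_equal(init_individual(sp, 20, seed = 1), rep(TRUE, 20))
  expect_error(init_individual(sp, 21, seed = 1), "exceeds")
})

test_that("initialization frequencies follow the key-weight law", {
  # two features, SP 0.8 vs 0.4, ninit 1: P(pick the first) =
  # P(u1^(1/0.8) > u2^(1/0.4)) = 1/(1 + 0.5) = 2/3
  set.seed(5)
  hits <- 0L
  for (r in 1:4000)
    hits <- hits + init_individual(c(0.8, 0.4), 1)[1]
  expect_equal(hits / 4000, 2 / 3, tolerance = 0.04)
  # equal SPs: uniform over features (chi-square goodness of fit)
  set.seed(6)
  counts <- integer(6)
  for (r in 1:3000)
    counts <- counts + init_individual(rep(0.6, 6), 2)
  expect_gt(chisq.test(counts)$p.value, 0.01)
})

test_that("fitness composition reproduces the stated arithmetic", {
  expect_equal(fitness_value(1, 1), 1.1 * exp(1))
  expect_equal(fitness_value(1, 1), 2.9903, tolerance = 1e-4)
  expect_equal(fitness_value(0.9, 0.8), exp(0.9) + 0.1 * exp(0.8))
  expect_equal(fitness_value(0.9, 0.8), 2.6822, tolerance = 1e-4)
})

test_that("wrapper fitness reaches the perfect-classification value", {
  ft <- balanced_table(5, 2, per_class = 30, seed = 2, mean_gap = 15,
                       noise_sd = 0.2)
  f <- ga_fitness(rep(TRUE, 5), ft, seed = 4)
  expect_equal(as.numeric(f), 1.1 * exp(1), tolerance = 1e-9)
  expect_equal(attr(f, "fm_all"), 1)
  expect_error(ga_fitness(rep(FALSE, 5), ft), "empty")
})

test_that("adaptive probability honors both branches and the limits", {
  rng <- c(0.4, 0.8)
  expect_equal(adaptive_probability(0.5, 1, 2, rng), 0.8)   # f < mean
  expect_equal(adaptive_probability(2, 1, 2, rng), 0.4)     # f = max
  expect_equal(adaptive_probability(1, 1, 2, rng), 0.8)     # f = mean
  expect_equal(adaptive_probability(1.5, 1, 2, rng), 0.6)   # midpoint
  expect_equal(adaptive_probability(3, 3, 3, rng), 0.4)     # degenerate pop
  expect_error(adaptive_probability(1, 2, 1, rng), "f_max")
})

test_that("COFAN keeps shared genes and the activation number", {
  p1 <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  p2 <- c(FALSE, TRUE, TRUE, TRUE, FALSE)
  set.seed(9)
  for (r in 1:50) {
    kids <- cofan(p1, p2)
    for (k in kids) {
      expect_equal(sum(k), 3)
      expect_true(all(which(k) %in% 1:4))        # within the parents' union
      expect_true(all(c(2, 3) %in% which(k)))    # homogeneous pair kept
    }
  }
  # identical parents reproduce themselves
  expect_equal(cofan(p1, p1), list(p1, p1))
  # disjoint parents still mix within the union
  d1 <- c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  d2 <- c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE)
  kids <- cofan(d1, d2)
  for (k in kids) {
    expect_equal(sum(k), 2)
    expect_true(all(which(k) %in% 1:4))
  }
  expect_error(cofan(p1, c(TRUE, rep(FALSE, 4))), "activation number")
})

test_that("MOFAN preserves cardinality across the probability range", {
  set.seed(4)
  parent <- c(rep(TRUE, 5), rep(FALSE, 15))
  expect_equal(mofan(parent, 0), parent)
  child1 <- mofan(parent, 1)
  expect_equal(sum(child1), 5)
  expect_equal(sum(child1 & parent), 0)          # all bits migrated
  for (r in 1:500) expect_equal(sum(mofan(parent, 0.4)), 5)
  # migration capped when few inactive bits remain
  tight <- c(rep(TRUE, 6), FALSE, FALSE)
  for (r in 1:50) expect_equal(sum(mofan(tight, 1)), 6)
})

test_that("no-invention invariant: children only use parental or mutated-in genes", {
  set.seed(12)
  for (r in 1:100) {
    m1 <- init_individual(rep(0.5, 30), 8)
    m2 <- init_individual(rep(0.5, 30), 8)
    kids <- cofan(m1, m2)
    union <- which(m1 | m2)
    for (k in kids) expect_true(all(which(k) %in% union))
  }
})

test_that("the GA is deterministic and monotone under elitism", {
  ft <- balanced_table(20, 3, per_class = 25, seed = 5)
  cfg <- ga_config(ninit = 3, population = 12, max_iterations = 6,
                   folds = 5, seed = 42)
  r1 <- run_gfsfan(ft, cfg)
  r2 <- run_gfsfan(ft, cfg)
  expect_identical(r1$selected, r2$selected)
  expect_identical(r1$history, r2$history)
  expect_true(all(diff(r1$history$best) >= -1e-12))
})

test_that("ninit equal to the feature count is a single-point search", {
  ft <- balanced_table(6, 2, per_class = 20, seed = 3)
  r <- run_gfsfan(ft, ga_config(ninit = 6, population = 8,
                                max_iterations = 5, folds = 4, seed = 1))
  expect_equal(sort(r$selected), sort(colnames(ft$x)))
  expect_error(run_gfsfan(ft, ga_config(ninit = 7, population = 8,
                                        max_iterations = 2)),
               "exceeds feature count")
})

test_that("the selected subset beats random subsets of the same size in SFI", {
  ft <- balanced_table(40, 4, per_class = 30, seed = 19)
  cfg <- ga_config(ninit = 4, population = 20, max_iterations = 12,
                   folds = 5, seed = 7)
  r <- run_gfsfan(ft, cfg)
  rep <- fisher_index(ft)
  s_sel <- sfi(rep, r$selected)
  set.seed(31)
  wins <- mean(vapply(1:1000, function(i)
    s_sel > sfi(rep, sample(40, 4)), TRUE))
  expect_gte(wins, 0.99)
})

test_that("Relief-F separates informative from noise and deduplicates", {
  # noise features sit near zero weight, far below informative ones, in
  # every seed; the sign of a near-zero weight is sampling noise, so the
  # ranking gap is the robust property
  for (s in 1:10) {
    ft <- balanced_table(6, 2, per_class = 40, classes = 2, seed = s,
                         mean_gap = 5)
    w <- relief_weights(ft)
    expect_lt(max(w[3:6]), 0.25 * min(w[1:2]))
    expect_lte(length(relief_filter(ft)), 6)
  }
  # exact duplicate: exactly one copy survives
  ft <- balanced_table(4, 2, per_class = 40, classes = 2, seed = 3)
  x <- cbind(ft$x, dup = ft$x[, 1])
  sel <- relief_filter(feature_table(x, ft$labels), corr_threshold = 0.95)
  expect_equal(sum(sel %in% c("F001", "dup")), 1)
})

test_that("SFS picks a deterministic separator first and never degrades", {
  ft <- balanced_table(8, 1, per_class = 30, classes = 2, seed = 6,
                       mean_gap = 10, noise_sd = 0.3)
  r <- sfs(ft, folds = 5, seed = 2)
  expect_equal(r$selected[1], "F001")
  expect_true(all(diff(r$fm_trajectory) >= -1e-12))
  # pure noise: stops early at a small subset near chance
  noise <- balanced_table(6, 0, per_class = 25, classes = 2, seed = 7)
  rn <- sfs(noise, folds = 5, seed = 2)
  expect_lte(length(rn$selected), 3)
  expect_lt(rn$fm, 0.75)
})
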