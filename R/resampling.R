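# Class rebalancing: ADASYN oversampling for classes below the target size,
# random undersampling (with replacement, redrawn per group) for classes
# above it, combined into an ensemble of k resampled groups that share the
# oversampled synthetic rows and differ only in the undersampled draws.
# The common per-class target is the geometric mean of the largest and
# smallest class sizes, rounded to the nearest integer.

#' ADASYN adaptive synthetic oversampling of one class
#'
#' For each sample of the minority class, the fraction of majority-class
#' neighbours among its `k_nn` nearest neighbours (in the full table) sets
#' its share of the synthetic budget: harder samples (more majority
#' neighbours) get more synthetic points. Each synthetic row is
#' `x + lambda * (x_nn - x)` with `lambda ~ U(0, 1)` and `x_nn` a random
#' minority neighbour, so it lies on the segment between two minority
#' points. If every share is zero the budget is spread uniformly. The exact
#' budget is met by largest-remainder allocation. Deterministic under
#' `seed`.
#'
#' @param table a `FeatureTable`.
#' @param class_c class label to oversample.
#' @param target_n desired class size (>= current size).
#' @param k_nn neighbourhood size (default 5). A class smaller than
#'   `k_nn + 1` falls back to random duplication with a warning.
#' @param seed integer seed.
#' @return Matrix of synthetic rows (possibly 0 rows).
#' @export
adasyn_oversample <- function(table, class_c, target_n, k_nn = 5, seed = 1) {
  stopifnot(inherits(table, "FeatureTable"))
  y <- table$labels
  idx_min <- which(y == class_c)
  n_min <- length(idx_min)
  if (!n_min) stop_gfsfan("class '", class_c, "' not present")
  G <- target_n - n_min
  if (G < 0) stop_gfsfan("target_n below current class size")
  x <- table$x
  if (G == 0) return(x[integer(0), , drop = FALSE])
  if (n_min < k_nn + 1) {
    warning("class '", class_c, "' smaller than k_nn + 1; duplicating randomly")
    return(with_seed(seed,
                     x[sample(idx_min, G, replace = TRUE), , drop = FALSE]))
  }
  with_seed(seed, {
    xm <- x[idx_min, , drop = FALSE]
    # k nearest neighbours of each minority sample in the whole table
    r <- numeric(n_min)
    nn_min <- matrix(0L, n_min, k_nn)            # minority-only neighbours
    for (i in seq_len(n_min)) {
      d <- sqrt(colSums((t(x) - x[idx_min[i], ])^2))
      d[idx_min[i]] <- Inf
      nb <- order(d)[seq_len(k_nn)]
      r[i] <- sum(y[nb] != class_c) / k_nn
      dm <- sqrt(colSums((t(xm) - x[idx_min[i], ])^2))
      dm[i] <- Inf
      nn_min[i, ] <- order(dm)[seq_len(min(k_nn, n_min - 1))]
    }
    share <- if (sum(r) == 0) rep(1 / n_min, n_min) else r / sum(r)
    g <- floor(share * G)
    rem <- G - sum(g)
    if (rem > 0) {
      extra <- order(-(share * G - g), seq_len(n_min))[seq_len(rem)]
      g[extra] <- g[extra] + 1
    }
    synth <- matrix(NA_real_, G, ncol(x))
    colnames(synth) <- colnames(x)
    row <- 1
    for (i in seq_len(n_min)) {
      if (g[i] == 0) next
      nb <- nn_min[i, sample.int(ncol(nn_min), g[i], replace = TRUE)]
      lam <- runif(g[i])
      synth[row:(row + g[i] - 1), ] <-
        xm[rep(i, g[i]), , drop = FALSE] +
        lam * (xm[nb, , drop = FALSE] - xm[rep(i, g[i]), , drop = FALSE])
      row <- row + g[i]
    }
    synth
  })
}

#' Geometric-mean resampling target
#' @param class_sizes integer vector of class sizes.
#' @return `round(sqrt(max * min))`.
#' @export
resample_target <- function(class_sizes) {
  round(sqrt(max(class_sizes) * min(class_sizes)))
}

#' Build an ensemble of k resampled, class-balanced groups
#'
#' Classes larger than the geometric-mean target are undersampled by random
#' sampling with replacement, redrawn for each of the `k` groups; classes
#' smaller than the target are oversampled once by ADASYN and the synthetic
#' rows are shared across all groups. Every class in every group ends at
#' exactly the target size.
#'
#' @param table a `FeatureTable` with >= 2 classes.
#' @param k number of groups (default 10).
#' @param seed integer seed; group and oversampling seeds derive from it.
#' @param k_nn ADASYN neighbourhood size.
#' @return A `ResampledEnsemble`: list with `groups` (list of
#'   `FeatureTable`), `target`, `k`, `seeds`.
#' @export
build_ensemble <- function(table, k = 10, seed = 1, k_nn = 5) {
  stopifnot(inherits(table, "FeatureTable"))
  y <- table$labels
  if (nlevels(y) < 2) stop_gfsfan("resampling needs >= 2 classes")
  sizes <- tabulate(y)
  target <- resample_target(sizes)
  lv <- levels(y)
  over <- list()                                  # shared synthetic rows
  for (c_i in which(sizes < target))
    over[[lv[c_i]]] <- adasyn_oversample(table, lv[c_i], target, k_nn,
                                         seed = derive_seed(seed, paste0("adasyn_", lv[c_i])))
  seeds <- vapply(seq_len(k), function(g) derive_seed(seed, paste0("group", g)), 0L)
  groups <- lapply(seq_len(k), function(g) {
    xs <- list(); ys <- list()
    with_seed(seeds[g], {
      for (c_i in seq_along(lv)) {
        idx <- which(y == lv[c_i])
        if (sizes[c_i] > target) {
          keep <- sample(idx, target, replace = TRUE)
          xs[[c_i]] <- table$x[keep, , drop = FALSE]
        } else {
          xs[[c_i]] <- rbind(table$x[idx, , drop = FALSE], over[[lv[c_i]]])
        }
        ys[[c_i]] <- rep(lv[c_i], target)
      }
    })
    feature_table(do.call(rbind, xs), factor(unlist(ys), levels = lv),
                  info = table$info)
  })
  structure(list(groups = groups, target = target, k = k, seeds = seeds),
            class = "ResampledEnsemble")
}

#' @export
print.ResampledEnsemble <- function(x, ...) {
  cat("ResampledEnsemble:", x$k, "groups,", x$target, "rows per class,",
      ncol(x$groups[[1]]$x), "features\n")
  invisible(x)
}
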