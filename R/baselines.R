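# Baseline feature selectors: the two-stage Relief-F + correlation filter
# and the sequential-forward-selection (SFS) wrapper, both sharing the
# F-measure criterion machinery used by the GA.

#' Relief-F relevance weights
#'
#' Multi-class Relief-F: for every sample, the k nearest hits (same class)
#' pull each feature's weight down by the normalized feature difference and
#' the k nearest misses of every other class push it up, weighted by the
#' class prior over the complement `P(c) / (1 - P(class_i))`. Features are
#' scaled by their range so weights are comparable.
#'
#' @param table a `FeatureTable` with >= 2 classes.
#' @param k neighbours per class (default 10, capped at class size - 1).
#' @return Named numeric weight per feature.
#' @export
relief_weights <- function(table, k = 10) {
  stopifnot(inherits(table, "FeatureTable"))
  y <- table$labels
  if (nlevels(y) < 2) stop_gfsfan("Relief-F needs >= 2 classes")
  x <- table$x
  n <- nrow(x); p <- ncol(x)
  rng <- apply(x, 2, function(col) max(col) - min(col))
  rng[rng == 0] <- 1
  xs <- sweep(x, 2, rng, "/")
  prior <- tabulate(y) / n
  names(prior) <- levels(y)
  W <- numeric(p)
  d2 <- as.matrix(dist(xs))^2
  diag(d2) <- Inf
  for (i in seq_len(n)) {
    ci <- as.character(y[i])
    for (cl in levels(y)) {
      idx <- which(y == cl & seq_len(n) != i)
      kk <- min(k, length(idx))
      if (!kk) next
      nb <- idx[order(d2[i, idx])[seq_len(kk)]]
      diffsum <- colMeans(abs(xs[nb, , drop = FALSE] -
                                matrix(xs[i, ], kk, p, byrow = TRUE)))
      if (cl == ci) W <- W - diffsum / n
      else W <- W + (prior[cl] / (1 - prior[ci])) * diffsum / n
    }
  }
  names(W) <- colnames(x)
  W
}

#' Two-stage Relief-F + correlation filter
#'
#' Stage 1 removes features with non-positive Relief-F weight (irrelevant
#' to the classification). Stage 2 removes redundancy: among features whose
#' pairwise absolute Pearson correlation exceeds `corr_threshold`, only the
#' highest-weight member survives (greedy by descending weight, so the
#' survivors are pairwise below the threshold).
#'
#' @param table a `FeatureTable`.
#' @param relief_k neighbours for [relief_weights()].
#' @param corr_threshold redundancy threshold on `|r|` (default 0.95).
#' @return Character vector of selected feature names.
#' @export
relief_filter <- function(table, relief_k = 10, corr_threshold = 0.95) {
  W <- relief_weights(table, k = relief_k)
  keep <- names(W)[W > 0]
  if (!length(keep)) return(character(0))
  ord <- keep[order(-W[keep])]
  x <- table$x[, ord, drop = FALSE]
  sds <- apply(x, 2, sd)
  selected <- character(0)
  for (f in ord) {
    if (length(selected)) {
      r <- vapply(selected, function(s) {
        if (sds[f] == 0 || sds[s] == 0) return(as.numeric(sds[f] == 0 && sds[s] == 0))
        abs(cor(x[, f], x[, s]))
      }, 0)
      if (any(r > corr_threshold)) next
    }
    selected <- c(selected, f)
  }
  selected
}

#' Sequential forward selection with the wrapper F-measure criterion
#'
#' Greedily adds the feature that most improves the mean per-class
#' F-measure of the LDA + naive-Bayes wrappers under stratified
#' cross-validation (averaged over resampled groups), stopping when the
#' best improvement falls to `tol` or below.
#'
#' @param data a `FeatureTable` or `ResampledEnsemble`.
#' @param max_features optional cap on the subset size.
#' @param tol minimum FM improvement to continue (default 1e-4).
#' @param folds,seed CV controls.
#' @param verbose print progress.
#' @return List with `selected` (feature names), `fm_trajectory` and the
#'   final `fm`.
#' @export
sfs <- function(data, max_features = NULL, tol = 1e-4, folds = 10, seed = 1,
                verbose = FALSE) {
  groups <- as_groups(data)
  M <- ncol(groups[[1]]$x)
  max_features <- max_features %||% M
  selected <- integer(0)
  best_fm <- 0
  traj <- numeric(0)
  repeat {
    cand <- setdiff(seq_len(M), selected)
    if (!length(cand) || length(selected) >= max_features) break
    fms <- vapply(cand, function(j)
      wrapper_fm(groups, c(selected, j), seed = seed, folds = folds)$fm_all, 0)
    j_best <- cand[which.max(fms)]
    if (max(fms) - best_fm <= tol && length(selected) > 0) break
    selected <- c(selected, j_best)
    best_fm <- max(fms)
    traj <- c(traj, best_fm)
    if (verbose) message(sprintf("SFS + %s -> FM %.4f",
                                 colnames(groups[[1]]$x)[j_best], best_fm))
  }
  list(selected = colnames(groups[[1]]$x)[selected],
       fm_trajectory = traj, fm = best_fm)
}
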