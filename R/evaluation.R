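# Per-class precision/recall/F-measure and cross-validated evaluation of
# feature subsets with the six study classifiers.

#' Per-class F-measure from a confusion matrix
#'
#' Rows are actual classes, columns predicted. `P_i = n_ii / colsum_i`,
#' `R_i = n_ii / rowsum_i`, `FM_i = 2 P_i R_i / (P_i + R_i)`; any zero
#' denominator yields 0 for that class (flagged).
#'
#' @param cm square numeric confusion matrix.
#' @return List with `fm` (per class), `precision`, `recall`, `fm_all`
#'   (mean over classes), `fm_min` and `flagged` (classes with zero
#'   denominators).
#' @export
f_measure <- function(cm) {
  cm <- as.matrix(cm)
  if (!length(cm) || nrow(cm) != ncol(cm)) stop_gfsfan("confusion matrix must be square and non-empty")
  if (sum(cm) == 0) stop_gfsfan("confusion matrix holds no predictions")
  d <- diag(cm)
  cs <- colSums(cm); rs <- rowSums(cm)
  P <- ifelse(cs > 0, d / cs, 0)
  R <- ifelse(rs > 0, d / rs, 0)
  fm <- ifelse(P + R > 0, 2 * P * R / (P + R), 0)
  names(fm) <- rownames(cm)
  list(fm = fm, precision = P, recall = R,
       fm_all = mean(fm), fm_min = min(fm),
       flagged = which(cs == 0 | rs == 0 | P + R == 0))
}

# mean per-class FM over the wrapper classifiers (LDA + Gaussian NB) and the
# ensemble groups, via stratified k-fold CV with confusions summed over
# folds. The engine behind both the GA fitness and the SFS criterion.
wrapper_fm <- function(groups, cols, seed, folds = 10,
                       wrappers = c("lda", "nb")) {
  fm_all_g <- fm_min_g <- numeric(length(groups))
  for (g in seq_along(groups)) {
    tab <- groups[[g]]
    x <- tab$x[, cols, drop = FALSE]
    y <- tab$labels
    fo <- stratified_folds(y, folds, seed = derive_seed(seed, paste0("folds", g)))
    fm_mat <- vapply(wrappers, function(w) {
      cm <- cv_confusion(x, y, fo, make_classifier(w, seed = seed))
      f_measure(cm)$fm
    }, numeric(nlevels(y)))
    fm_cls <- rowMeans(fm_mat)
    fm_all_g[g] <- mean(fm_cls)
    fm_min_g[g] <- min(fm_cls)
  }
  list(fm_all = mean(fm_all_g), fm_min = mean(fm_min_g))
}

as_groups <- function(data) {
  if (inherits(data, "ResampledEnsemble")) data$groups
  else if (inherits(data, "FeatureTable")) list(data)
  else stop_gfsfan("expected a FeatureTable or ResampledEnsemble")
}

#' Cross-validated evaluation of a feature subset
#'
#' Stratified k-fold cross-validation on the subset columns with one of the
#' six study classifiers; fold confusions are summed before computing
#' per-class F-measures.
#'
#' @param table a `FeatureTable`.
#' @param subset feature indices or names (default: all features).
#' @param classifier one of `"centroid"`, `"knn"`, `"lda"`, `"nb"`, `"rf"`,
#'   `"svm"`.
#' @param folds number of CV folds (default 10).
#' @param seed integer seed (fold assignment and stochastic learners).
#' @return An `EvaluationResult`: list with the confusion matrix, per-class
#'   `fm`, `fm_all`, `fm_min`, `classifier` and `subset`.
#' @export
evaluate_subset <- function(table, subset = NULL, classifier = "knn",
                            folds = 10, seed = 1) {
  stopifnot(inherits(table, "FeatureTable"))
  cols <- subset %||% seq_len(ncol(table$x))
  if (is.character(cols)) cols <- match(cols, colnames(table$x))
  if (!length(cols) || anyNA(cols)) stop_gfsfan("empty or unknown feature subset")
  y <- table$labels
  fo <- stratified_folds(y, folds, seed = derive_seed(seed, "folds"))
  cm <- cv_confusion(table$x[, cols, drop = FALSE], y, fo,
                     make_classifier(classifier, seed = seed))
  res <- f_measure(cm)
  structure(list(confusion = cm, fm = res$fm, fm_all = res$fm_all,
                 fm_min = res$fm_min, classifier = classifier,
                 subset = colnames(table$x)[cols]),
            class = "EvaluationResult")
}

#' @export
print.EvaluationResult <- function(x, ...) {
  cat(sprintf("EvaluationResult [%s, %d features]: FM_all %.3f, FM_min %.3f\n",
              x$classifier, length(x$subset), x$fm_all, x$fm_min))
  invisible(x)
}

#' The seven study sensor combinations
#' @return Named list mapping combination id to modality/sensor filters.
#' @export
study_combinations <- function() {
  list(sEMG = list(modality = "emg"),
       ACC = list(modality = "acc"),
       GYR = list(modality = "gyr"),
       Joint = list(modality = "joint"),
       IMU = list(modality = c("acc", "gyr")),
       `sEMG+IMU` = list(modality = c("emg", "acc", "gyr")),
       All = list(modality = c("emg", "acc", "gyr", "joint")))
}

#' Feature-selector x classifier sweep over sensor combinations
#'
#' Filters the feature table by modality provenance into sensor
#' combinations, optionally runs a feature selector per combination, and
#' evaluates each classifier on the (selected) columns, yielding a grid of
#' feature counts (FN) and F-measures (FM).
#'
#' @param table a `FeatureTable` whose `info` carries modality provenance.
#' @param combinations named list of filters (`modality`, optionally
#'   `sensor`); default [study_combinations()] restricted to modalities
#'   present.
#' @param selector `NULL` (use all features) or a
#'   `function(FeatureTable) -> column names/indices`.
#' @param classifiers character vector of classifier ids.
#' @param folds,seed CV controls.
#' @return data.frame with columns `combination`, `classifier`, `fn`, `fm`,
#'   `fm_min`.
#' @export
sensor_combination_sweep <- function(table, combinations = NULL,
                                     selector = NULL,
                                     classifiers = c("knn", "rf", "svm"),
                                     folds = 10, seed = 1) {
  stopifnot(inherits(table, "FeatureTable"))
  if (is.null(combinations)) {
    present <- unique(table$info$modality)
    combinations <- Filter(function(f) all(f$modality %in% present),
                           study_combinations())
  }
  rows <- list()
  for (cb in names(combinations)) {
    filt <- combinations[[cb]]
    keep <- table$info$modality %in% filt$modality
    if (!is.null(filt$sensor)) keep <- keep & table$info$sensor %in% filt$sensor
    if (!any(keep)) stop_gfsfan("combination '", cb, "' selects no features")
    sub <- ft_subset(table, features = which(keep))
    cols <- if (is.null(selector)) seq_len(ncol(sub$x)) else selector(sub)
    for (cl in classifiers) {
      res <- evaluate_subset(sub, cols, classifier = cl, folds = folds,
                             seed = seed)
      rows[[length(rows) + 1]] <- data.frame(
        combination = cb, classifier = cl, fn = length(res$subset),
        fm = res$fm_all, fm_min = res$fm_min, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
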