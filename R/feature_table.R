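# FeatureTable: windows x features matrix with class labels and per-feature
# provenance (sensor, channel, modality, feature name, component index).

#' Construct a feature table
#'
#' @param x numeric matrix, one row per window/sample, one column per feature.
#' @param labels factor (or coercible) of class labels, one per row.
#' @param info optional data.frame with one row per feature; columns `name`,
#'   `modality`, `sensor`, `channel`, `feature`, `component`. Built from
#'   column names when omitted.
#' @param norm optional normalization state as returned by
#'   [normalize_minmax()].
#' @return An object of class `FeatureTable`.
#' @export
feature_table <- function(x, labels, info = NULL, norm = NULL) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop_gfsfan("feature matrix must be numeric")
  if (any(!is.finite(x))) stop_gfsfan("feature matrix contains non-finite entries")
  labels <- as.factor(labels)
  if (length(labels) != nrow(x))
    stop_gfsfan("labels length (", length(labels), ") != rows (", nrow(x), ")")
  if (is.null(colnames(x))) colnames(x) <- sprintf("F%03d", seq_len(ncol(x)))
  if (is.null(info)) {
    info <- data.frame(name = colnames(x), modality = NA_character_,
                       sensor = NA_character_, channel = NA_character_,
                       feature = NA_character_, component = NA_integer_,
                       stringsAsFactors = FALSE)
  }
  if (nrow(info) != ncol(x)) stop_gfsfan("info must have one row per feature")
  structure(list(x = x, labels = labels, info = info, norm = norm),
            class = "FeatureTable")
}

#' @export
print.FeatureTable <- function(x, ...) {
  cat("FeatureTable:", nrow(x$x), "windows x", ncol(x$x), "features\n")
  cat("classes:", paste(sprintf("%s (%d)", levels(x$labels),
                                tabulate(x$labels)), collapse = ", "), "\n")
  if (!is.null(x$norm)) cat("min-max normalized\n")
  invisible(x)
}

#' @export
dim.FeatureTable <- function(x) dim(x$x)

#' Subset a feature table by features and/or rows
#' @param table a `FeatureTable`.
#' @param features column indices or names to keep (default all).
#' @param rows row indices to keep (default all).
#' @return A `FeatureTable`.
#' @export
ft_subset <- function(table, features = NULL, rows = NULL) {
  j <- if (is.null(features)) seq_len(ncol(table$x)) else features
  if (is.character(j)) j <- match(j, colnames(table$x))
  if (anyNA(j)) stop_gfsfan("unknown feature name(s)")
  i <- if (is.null(rows)) seq_len(nrow(table$x)) else rows
  feature_table(table$x[i, j, drop = FALSE], droplevels(table$labels[i]),
                info = table$info[j, , drop = FALSE])
}

#' Min-max normalize feature columns
#'
#' Columns are mapped by `(x - min) / (max - min)` with the minima/maxima
#' taken from `fit_on` rows only (so held-out folds can be transformed with
#' training-fold parameters). Constant columns map to 0 and are flagged.
#' Out-of-range values on new data are not clipped.
#'
#' @param table a `FeatureTable`.
#' @param fit_on row indices used to fit the transform (default: all rows).
#' @param params optional previously fitted parameters (list with `min`,
#'   `max`) to apply instead of fitting.
#' @return A `FeatureTable` with `norm` holding `min`, `max` and a
#'   `constant` flag per feature.
#' @export
normalize_minmax <- function(table, fit_on = NULL, params = NULL) {
  x <- table$x
  if (is.null(params)) {
    i <- fit_on %||% seq_len(nrow(x))
    if (!length(i)) stop_gfsfan("fit set is empty")
    mn <- apply(x[i, , drop = FALSE], 2, min)
    mx <- apply(x[i, , drop = FALSE], 2, max)
  } else {
    mn <- params$min; mx <- params$max
  }
  rng <- mx - mn
  const <- rng == 0
  rng[const] <- 1
  out <- sweep(sweep(x, 2, mn, "-"), 2, rng, "/")
  out[, const] <- 0
  feature_table(out, table$labels, info = table$info,
                norm = list(min = mn, max = mx, constant = const))
}
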