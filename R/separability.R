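# Fisher-Index class separability: ratio of between-class to within-class
# scatter, computed feature-wise (traces of 1x1 scatter matrices, so the sum
# over a feature set equals the trace of the multivariate scatter ratio's
# numerator/denominator terms).

#' Fisher Index of every feature
#'
#' For each feature, `Sb = sum_i p_i (m_i - m)^2` and
#' `Sw = sum_i p_i Var_i` with class priors `p_i` (class frequencies),
#' class means `m_i`, overall mean `m = sum_i p_i m_i` and population
#' (within-class) variances `Var_i`; `FI = Sb / Sw`. Features whose
#' within-class variance vanishes in every class get `FI = Inf` and rank
#' first (flagged).
#'
#' @param table a `FeatureTable` with >= 2 classes, each with >= 2 samples.
#' @return A `SeparabilityReport`: list with `fi` (named vector), `ranking`
#'   (feature indices, descending FI, ties broken by original index) and
#'   `flagged` (features with zero within-class scatter).
#' @export
fisher_index <- function(table) {
  stopifnot(inherits(table, "FeatureTable"))
  y <- table$labels
  if (nlevels(y) < 2) stop_gfsfan("Fisher Index needs >= 2 classes")
  if (any(tabulate(y) < 2)) stop_gfsfan("every class needs >= 2 samples")
  x <- table$x
  n <- nrow(x)
  p <- tabulate(y) / n
  K <- nlevels(y)
  cm <- matrix(0, K, ncol(x))
  cv <- matrix(0, K, ncol(x))
  for (k in seq_len(K)) {
    xi <- x[y == levels(y)[k], , drop = FALSE]
    cm[k, ] <- colMeans(xi)
    cv[k, ] <- colMeans(xi^2) - cm[k, ]^2        # population variance
  }
  m <- drop(p %*% cm)
  sb <- drop(p %*% (sweep(cm, 2, m)^2))
  sw <- drop(p %*% cv)
  fi <- ifelse(sw > 0, sb / sw, ifelse(sb > 0, Inf, 0))
  names(fi) <- colnames(x)
  ranking <- order(-fi, seq_along(fi))           # ties -> original index
  structure(list(fi = fi, ranking = ranking,
                 flagged = which(sw == 0 & sb > 0)),
            class = "SeparabilityReport")
}

#' @export
print.SeparabilityReport <- function(x, ...) {
  cat("SeparabilityReport:", length(x$fi), "features\n")
  top <- x$ranking[seq_len(min(5, length(x$fi)))]
  cat("top FI:", paste(sprintf("%s=%.3g", names(x$fi)[top], x$fi[top]),
                       collapse = ", "), "\n")
  invisible(x)
}

#' Sum of Fisher Indices over a feature set
#'
#' @param report a `SeparabilityReport` from [fisher_index()].
#' @param feature_set indices or names of features (empty set gives 0).
#' @return Scalar SFI.
#' @export
sfi <- function(report, feature_set) {
  if (!length(feature_set)) return(0)
  if (is.character(feature_set)) {
    feature_set <- match(feature_set, names(report$fi))
    if (anyNA(feature_set)) stop_gfsfan("feature set contains unknown names")
  }
  sum(report$fi[feature_set])
}
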