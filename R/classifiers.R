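# Uniform classifier contract: classifier_fit(model_spec, x, y) returns a
# model; classifier_predict(model, x) returns labels. The four light
# classifiers (nearest-centroid, 1-NN, LDA, Gaussian naive Bayes) are
# implemented natively and vectorized because they run inside the genetic
# algorithm's wrapper loop; random forest and the linear SVM enter through
# adapters to randomForest and e1071.

ridge_solve <- function(S) {
  r <- 1e-8 * mean(diag(S)) + 1e-12
  solve(S + r * diag(nrow(S)))
}

fit_centroid <- function(x, y) {
  lv <- levels(y)
  M <- t(vapply(lv, function(l) colMeans(x[y == l, , drop = FALSE]),
                numeric(ncol(x))))
  list(type = "centroid", M = M, levels = lv)
}

fit_lda <- function(x, y) {
  lv <- levels(y)
  n <- nrow(x); p <- ncol(x); K <- length(lv)
  M <- matrix(0, K, p)
  S <- matrix(0, p, p)
  prior <- numeric(K)
  for (k in seq_len(K)) {
    xi <- x[y == lv[k], , drop = FALSE]
    M[k, ] <- colMeans(xi)
    xc <- sweep(xi, 2, M[k, ])
    S <- S + crossprod(xc)
    prior[k] <- nrow(xi) / n
  }
  S <- S / max(1, n - K)
  W <- ridge_solve(S)
  A <- M %*% W                                  # K x p
  b <- -0.5 * rowSums(A * M) + log(prior)
  list(type = "lda", A = A, b = b, levels = lv)
}

fit_gnb <- function(x, y) {
  lv <- levels(y)
  K <- length(lv); p <- ncol(x)
  M <- V <- matrix(0, K, p)
  prior <- numeric(K)
  for (k in seq_len(K)) {
    xi <- x[y == lv[k], , drop = FALSE]
    M[k, ] <- colMeans(xi)
    V[k, ] <- pmax(colMeans(xi^2) - M[k, ]^2, 1e-9)
    prior[k] <- nrow(xi) / nrow(x)
  }
  list(type = "gnb", M = M, V = V, logprior = log(prior), levels = lv)
}

predict_native <- function(model, x) {
  x <- as.matrix(x)
  sc <- switch(model$type,
    centroid = {
      d2 <- outer(rowSums(x^2), rowSums(model$M^2), "+") -
        2 * x %*% t(model$M)
      -d2
    },
    lda = sweep(x %*% t(model$A), 2, model$b, "+"),
    gnb = {
      K <- nrow(model$M)
      s <- matrix(0, nrow(x), K)
      for (k in seq_len(K)) {
        z <- sweep(x, 2, model$M[k, ])
        s[, k] <- model$logprior[k] -
          0.5 * (z^2 %*% (1 / model$V[k, ])) -
          0.5 * sum(log(2 * pi * model$V[k, ]))
      }
      s
    },
    knn1 = {
      d2 <- outer(rowSums(x^2), rowSums(model$train^2), "+") -
        2 * x %*% t(model$train)
      return(factor(model$y[max.col(-d2, ties.method = "first")],
                    levels = model$levels))
    },
    stop_gfsfan("unknown native model"))
  factor(model$levels[max.col(sc, ties.method = "first")],
         levels = model$levels)
}

#' Construct a classifier under the uniform fit/predict contract
#'
#' Available classifiers and their fixed hyperparameters: `"centroid"`
#' (nearest class mean), `"knn"` (k = 1), `"lda"`, `"nb"` (Gaussian naive
#' Bayes), `"rf"` (random forest, 8 trees, seeded) and `"svm"` (linear
#' kernel, C = 1, one-against-the-rest).
#'
#' @param name classifier id.
#' @param seed integer seed used by the stochastic learners (rf).
#' @return List with `fit(x, y)` and `predict(model, x)` functions.
#' @export
make_classifier <- function(name, seed = 1) {
  switch(name,
    centroid = list(fit = fit_centroid, predict = predict_native),
    lda = list(fit = fit_lda, predict = predict_native),
    nb = list(fit = fit_gnb, predict = predict_native),
    knn = list(
      fit = function(x, y) list(type = "knn1", train = as.matrix(x), y = y,
                                levels = levels(y)),
      predict = predict_native),
    rf = list(
      fit = function(x, y) with_seed(seed,
        randomForest::randomForest(x = as.data.frame(x), y = y, ntree = 8)),
      predict = function(model, x)
        predict(model, newdata = as.data.frame(x))),
    svm = list(
      fit = function(x, y) {
        lv <- levels(y)
        models <- lapply(lv, function(l) {
          yy <- factor(ifelse(y == l, "pos", "neg"), levels = c("pos", "neg"))
          m <- e1071::svm(as.matrix(x), yy, kernel = "linear", cost = 1,
                          scale = FALSE)
          # libsvm decision values are signed toward the first class seen in
          # the training data, not the first factor level
          m$pos_sign <- if (m$levels[m$labels[1]] == "pos") 1 else -1
          m
        })
        list(type = "ovr_svm", models = models, levels = lv)
      },
      predict = function(model, x) {
        dec <- vapply(model$models, function(m) {
          pr <- predict(m, as.matrix(x), decision.values = TRUE)
          m$pos_sign * drop(attr(pr, "decision.values"))
        }, numeric(nrow(as.matrix(x))))
        if (is.null(dim(dec))) dec <- matrix(dec, nrow = 1)
        factor(model$levels[max.col(dec, ties.method = "first")],
               levels = model$levels)
      }),
    stop_gfsfan("unknown classifier '", name, "'"))
}

#' Stratified cross-validation fold assignment
#'
#' @param y factor of labels.
#' @param k number of folds.
#' @param seed integer seed.
#' @return Integer fold id per sample; every class is spread as evenly as
#'   possible across folds.
#' @export
stratified_folds <- function(y, k = 10, seed = 1) {
  folds <- integer(length(y))
  with_seed(seed, {
    for (l in levels(y)) {
      idx <- which(y == l)
      folds[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
    }
  })
  folds
}

# confusion matrix summed over CV folds (rows = actual, cols = predicted)
cv_confusion <- function(x, y, folds, clf) {
  lv <- levels(y)
  cm <- matrix(0L, length(lv), length(lv), dimnames = list(lv, lv))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    if (length(unique(y[tr])) < length(lv)) next  # degenerate fold: skip
    model <- clf$fit(x[tr, , drop = FALSE], y[tr])
    pred <- clf$predict(model, x[!tr, , drop = FALSE])
    cm <- cm + table(factor(y[!tr], levels = lv), factor(pred, levels = lv))
  }
  cm
}
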