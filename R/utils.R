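#' @keywords internal
"_PACKAGE"

#' @importFrom stats aggregate ar coef cor fft median quantile rnorm runif sd var predict
#' @importFrom utils head read.csv write.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_gfsfan <- function(..., class = "gfsfan_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_gfsfan(name, " must be a finite numeric scalar")
  if (positive && x <= 0) stop_gfsfan(name, " must be positive")
  invisible(x)
}

#' Derive a reproducible sub-stream seed
#'
#' All randomness in the package flows from user-supplied integer seeds.
#' Pipeline stages and resampling groups draw their own seeds from a global
#' seed plus a stream name, so stages are independently reproducible.
#'
#' @param seed integer global seed.
#' @param stream character stream name (e.g. a stage name).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)) * 131)
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
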