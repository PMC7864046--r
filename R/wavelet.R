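# Discrete wavelet transform with the sym4 (Symlet-4, least-asymmetric
# Daubechies, 8-tap) basis, used for the wavelet-energy features. Symmetric
# (half-sample mirror) boundary extension is the default; periodized
# extension gives an orthonormal transform satisfying Parseval exactly and
# backs the energy-conservation property test.

sym4_dec_lo <- c(-0.07576571478927333, -0.02963552764599851, 0.49761866763201545,
                 0.80373875180591614, 0.29785779560527736, -0.09921954357684722,
                 -0.01260396726203783, 0.03222310060404270)
sym4_dec_hi <- c(-0.03222310060404270, -0.01260396726203783, 0.09921954357684722,
                 0.29785779560527736, -0.80373875180591614, 0.49761866763201545,
                 0.02963552764599851, -0.07576571478927333)

dwt_step <- function(x, mode = c("symmetric", "periodization")) {
  mode <- match.arg(mode)
  n <- length(x)
  f <- length(sym4_dec_lo)
  if (mode == "symmetric") {
    ext <- c(rev(x[seq_len(f - 1)]), x, rev(x)[seq_len(f - 1)])
    conv_ds <- function(filt) {
      y <- stats::convolve(ext, rev(filt), type = "open")
      y[seq(f + 1, by = 2, length.out = floor((n + f - 1) / 2))]
    }
  } else {
    if (n %% 2 == 1) { x <- c(x, x[n]); n <- n + 1 }
    ext <- c(x[(n - f + 2):n], x, x[seq_len(f)])
    conv_ds <- function(filt) {
      y <- stats::convolve(ext, rev(filt), type = "open")
      y[seq(f + 4, by = 2, length.out = n / 2)]
    }
  }
  list(cA = conv_ds(sym4_dec_lo), cD = conv_ds(sym4_dec_hi))
}

#' Multilevel sym4 wavelet decomposition
#'
#' @param x numeric signal.
#' @param level decomposition depth (default 4).
#' @param mode boundary handling: `"symmetric"` (default) or
#'   `"periodization"` (orthonormal; energy-preserving).
#' @return List with approximation `A` (deepest level) and details
#'   `D[[level]] ... D[[1]]` (`D[[k]]` = level-k detail).
#' @export
wavedec_sym4 <- function(x, level = 4, mode = "symmetric") {
  min_len <- 2^level * length(sym4_dec_lo) / 4
  if (length(x) < min_len)
    stop_gfsfan("window too short for a level-", level,
                " sym4 decomposition; need at least ", ceiling(min_len),
                " samples")
  D <- vector("list", level)
  cur <- x
  for (lev in seq_len(level)) {
    st <- dwt_step(cur, mode)
    D[[lev]] <- st$cD
    cur <- st$cA
  }
  list(A = cur, D = D)
}

#' Wavelet-coefficient energies (EWC)
#'
#' Energy (mean squared coefficient) of the level-4 approximation and all
#' four details of the sym4 decomposition, in the fixed order A4, D4, D3,
#' D2, D1.
#'
#' @param x numeric window.
#' @param mode boundary mode passed to [wavedec_sym4()].
#' @return Named numeric vector `EWC_A4, EWC_D4, EWC_D3, EWC_D2, EWC_D1`.
#' @export
wavelet_energies <- function(x, mode = "symmetric") {
  w <- wavedec_sym4(x, level = 4, mode = mode)
  out <- c(mean(w$A^2), mean(w$D[[4]]^2), mean(w$D[[3]]^2),
           mean(w$D[[2]]^2), mean(w$D[[1]]^2))
  names(out) <- c("EWC_A4", "EWC_D4", "EWC_D3", "EWC_D2", "EWC_D1")
  out
}
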