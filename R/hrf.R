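# Canonical double-gamma hemodynamic response.

#' Double-gamma HRF
#'
#' `h(t) = dgamma(t, peak) - ratio * dgamma(t, undershoot)`, normalized to a
#' peak of 1. Defaults are the canonical peak 6 s, undershoot 16 s, ratio
#' 1/6.
#' @param t time points in seconds.
#' @param peak,undershoot gamma shape parameters (seconds to peak/undershoot).
#' @param ratio undershoot amplitude ratio.
#' @export
hrf_double_gamma <- function(t, peak = 6, undershoot = 16, ratio = 1 / 6) {
  h <- stats::dgamma(t, shape = peak) - ratio * stats::dgamma(t, shape = undershoot)
  h / max(stats::dgamma(seq(0, 40, by = 0.01), shape = peak))
}

#' Convolve neural time courses with the HRF
#'
#' Causal discrete convolution at the sampling interval `tr`, truncated to
#' the input length.
#' @param x numeric matrix, time in rows.
#' @param tr sampling interval in seconds.
#' @param duration_s HRF kernel support in seconds.
#' @param ... passed to [hrf_double_gamma()].
#' @export
convolve_hrf <- function(x, tr, duration_s = 32, ...) {
  x <- as.matrix(x)
  k <- hrf_double_gamma(seq(0, duration_s, by = tr), ...)
  n <- nrow(x)
  y <- matrix(0, n, ncol(x))
  for (j in seq_along(k)) {
    if (j > n) break
    y[j:n, ] <- y[j:n, , drop = FALSE] + k[j] * x[seq_len(n - j + 1), , drop = FALSE]
  }
  dimnames(y) <- dimnames(x)
  y
}
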