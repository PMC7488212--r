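# Condition-specific temporal filtering before CF fitting. Stimulus runs
# receive only linear detrending (a bandpass would remove the
# stimulus-locked signal itself); resting-state runs are additionally
# bandpass filtered to 0.01-0.1 Hz.

#' Remove the per-unit linear trend
#'
#' Subtracts the least-squares line (intercept + slope over volume index)
#' from every column, so output columns have zero mean and zero linear
#' trend to machine precision. Idempotent.
#' @param ts a `cf_ts` or numeric matrix (time in rows).
#' @return object of the same type.
#' @export
detrend_linear <- function(ts) {
  x <- if (inherits(ts, "cf_ts")) ts$data else as.matrix(ts)
  n <- nrow(x)
  assert_that(n >= 3, "detrending needs >= 3 volumes, got %d", n)
  t0 <- seq_len(n) - (n + 1) / 2            # centered time, orthogonal to intercept
  slope <- crossprod(t0, x) / sum(t0^2)     # 1 x p
  out <- x - rep(colMeans(x), each = n) - outer(t0, drop(slope))
  if (inherits(ts, "cf_ts")) { ts$data <- out; ts } else out
}

#' Zero-phase bandpass filter
#'
#' Frequency-domain mask with gain 1 on `[f_lo, f_hi]`, raised-cosine
#' transitions of width `transition_hz` outside the band, and 0 elsewhere
#' (DC always removed). Being a real symmetric mask, the filter is exactly
#' zero phase.
#' @param ts a `cf_ts` (TR taken from the object) or numeric matrix.
#' @param f_lo,f_hi passband edges in Hz (defaults 0.01 and 0.1).
#' @param tr sampling interval in seconds; required for plain matrices.
#' @param transition_hz raised-cosine transition width (default 0.005 Hz).
#' @export
bandpass <- function(ts, f_lo = 0.01, f_hi = 0.1, tr = NULL,
                     transition_hz = 0.005) {
  x <- if (inherits(ts, "cf_ts")) ts$data else as.matrix(ts)
  tr <- if (inherits(ts, "cf_ts")) ts$tr else tr
  assert_that(!is.null(tr) && tr > 0, "TR must be known for bandpass filtering")
  nyq <- 1 / (2 * tr)
  assert_that(f_lo > 0 && f_lo < f_hi && f_hi < nyq,
              "band [%g, %g] Hz incompatible with TR %g s (Nyquist %g Hz)",
              f_lo, f_hi, tr, nyq)
  n <- nrow(x)
  fr <- (seq_len(n) - 1) / (n * tr)
  fr <- pmin(fr, 1 / tr - fr)               # fold to [0, Nyquist]
  H <- raised_cosine_gain(fr, f_lo, f_hi, transition_hz)
  H[fr == 0] <- 0
  out <- Re(stats::mvfft(stats::mvfft(x) * H, inverse = TRUE)) / n
  dimnames(out) <- dimnames(x)
  if (inherits(ts, "cf_ts")) { ts$data <- out; ts } else out
}

raised_cosine_gain <- function(f, f_lo, f_hi, tw) {
  g <- numeric(length(f))
  g[f >= f_lo & f <= f_hi] <- 1
  lo_ramp <- f > f_lo - tw & f < f_lo
  g[lo_ramp] <- 0.5 * (1 + cos(pi * (f_lo - f[lo_ramp]) / tw))
  hi_ramp <- f > f_hi & f < f_hi + tw
  g[hi_ramp] <- 0.5 * (1 + cos(pi * (f[hi_ramp] - f_hi) / tw))
  g
}

#' Condition-appropriate preprocessing
#'
#' Stimulus runs: linear detrend only. Resting-state runs: linear detrend
#' followed by a 0.01-0.1 Hz zero-phase bandpass.
#' @param ts a `cf_ts` whose `condition` tag selects the path.
#' @param f_lo,f_hi resting-state band (Hz).
#' @export
preprocess_run <- function(ts, f_lo = 0.01, f_hi = 0.1) {
  assert_that(inherits(ts, "cf_ts"), "preprocess_run expects a cf_ts")
  out <- detrend_linear(ts)
  if (ts$condition == "rest") out <- bandpass(out, f_lo = f_lo, f_hi = f_hi)
  out
}
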