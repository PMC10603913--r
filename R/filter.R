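## Low-pass Butterworth design and zero-phase filtering.
##
## The pre-installed stack has no DSP package, so the classical design is
## implemented here: analog Butterworth prototype poles, frequency prewarp,
## bilinear transform. Coefficients and the forward-backward filter are
## verified in the test suite against values frozen from an independent
## reference implementation.

poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (root in r) p <- c(p, 0i) - c(0i, p * root)
  p
}

#' Low-pass Butterworth filter coefficients
#'
#' Digital IIR coefficients for a low-pass Butterworth filter via the
#' bilinear transform, for a series sampled at `fs` samples per minute.
#'
#' @param order Filter order (>= 1).
#' @param cutoff Cutoff frequency in cycles per minute; must lie strictly
#'   between 0 and the Nyquist frequency `fs / 2`.
#' @param fs Sampling rate in samples per minute (default 1).
#' @return A list with numerator `b` and denominator `a` (length `order + 1`,
#'   `a[1] = 1`).
#' @export
butter_lowpass <- function(order, cutoff, fs = 1) {
  if (order < 1) stop("order must be >= 1")
  wn <- cutoff / (fs / 2)
  if (wn <= 0 || wn >= 1) stop("cutoff must lie in (0, Nyquist)")
  k <- seq_len(order)
  p_proto <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  fs2 <- 2                               # internal bilinear sampling rate
  warped <- 2 * fs2 * tan(pi * wn / fs2) # prewarped analog cutoff
  p <- warped * p_proto
  gain <- warped^order
  ## bilinear transform s -> 2*fs2*(z-1)/(z+1)
  pz <- (2 * fs2 + p) / (2 * fs2 - p)
  gain_z <- gain * Re(1 / prod(2 * fs2 - p))
  a <- Re(poly_from_roots(pz))
  b <- gain_z * Re(poly_from_roots(rep(-1 + 0i, order)))
  list(b = b, a = a)
}

## Direct-form-II-transposed IIR filter with initial state `zi`.
lfilter <- function(b, a, x, zi = NULL) {
  n <- max(length(a), length(b))
  b <- c(b, numeric(n - length(b)))
  a <- c(a, numeric(n - length(a)))
  b <- b / a[1]; a <- a / a[1]
  z <- if (is.null(zi)) numeric(n - 1) else zi
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    xi <- x[i]
    yi <- b[1] * xi + z[1]
    if (n > 2) {
      for (j in 1:(n - 2)) z[j] <- b[j + 1] * xi - a[j + 1] * yi + z[j + 1]
    }
    z[n - 1] <- b[n] * xi - a[n] * yi
    y[i] <- yi
  }
  y
}

## Steady-state filter state for a unit step input (lfilter_zi).
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, numeric(n - length(b)))
  a <- c(a, numeric(n - length(a)))
  b <- b / a[1]; a <- a / a[1]
  if (n == 1) return(numeric(0))
  comp_t <- t(rbind(-a[2:n], if (n > 2) diag(1, n - 2, n - 1) else NULL))
  B <- b[2:n] - a[2:n] * b[1]
  solve(diag(n - 1) - comp_t, B)
}

#' Zero-phase (forward-backward) filtering
#'
#' Applies the IIR filter forward and backward so that the net phase response
#' is zero, with odd-reflection edge padding and steady-state initial
#' conditions so that a constant series passes through exactly.
#'
#' @param b,a Filter coefficients from [butter_lowpass()].
#' @param x Numeric series without gaps.
#' @param padlen Edge padding length (default `3 * max(length(a), length(b))`).
#' @return The filtered series, same length as `x`.
#' @export
filtfilt <- function(b, a, x, padlen = 3 * max(length(a), length(b))) {
  n <- length(x)
  if (n <= padlen) stop("series too short for the filter warm-up (need > ",
                        padlen, " samples)")
  ## odd reflection about the end points
  pre <- 2 * x[1] - x[(padlen + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - padlen)]
  ext <- c(pre, x, post)
  zi <- lfilter_zi(b, a)
  y <- lfilter(b, a, ext, zi * ext[1])
  y <- rev(lfilter(b, a, rev(y), zi * y[length(y)]))
  y[(padlen + 1):(padlen + n)]
}

#' Smoothing configuration
#'
#' @param order Butterworth order (default 2).
#' @param cutoff Low-pass cutoff in cycles per minute; the default 1/30
#'   preserves events of ~20 min and longer while removing minute-scale
#'   jitter.
#' @param zero_phase Use forward-backward filtering (default `TRUE`).
#' @return An object of class `smoothing_config`.
#' @export
smoothing_config <- function(order = 2, cutoff = 1 / 30, zero_phase = TRUE) {
  if (order < 1) stop("order must be >= 1")
  structure(list(order = order, cutoff = cutoff, zero_phase = zero_phase),
            class = "smoothing_config")
}

#' Butterworth-smooth a gapless series
#'
#' @param x Numeric series (one gapless section; run per section).
#' @param config A [smoothing_config()].
#' @param fs Sampling rate in samples per minute.
#' @return The smoothed series, or `x` unchanged (with a warning) when the
#'   section is shorter than the filter warm-up.
#' @export
smooth_series <- function(x, config = smoothing_config(), fs = 1) {
  if (anyNA(x)) stop("smooth_series requires a gapless section")
  coefs <- butter_lowpass(config$order, config$cutoff, fs)
  padlen <- 3 * max(length(coefs$a), length(coefs$b))
  if (length(x) <= padlen) {
    warning("section shorter than filter warm-up; returned unsmoothed")
    return(x)
  }
  if (config$zero_phase) {
    filtfilt(coefs$b, coefs$a, x, padlen)
  } else {
    lfilter(coefs$b, coefs$a, x, lfilter_zi(coefs$b, coefs$a) * x[1])
  }
}

#' z-score normalisation
#'
#' Transforms a series to zero mean and unit variance (population
#' convention, dividing by `sqrt(mean((x - mean(x))^2))`).
#'
#' @param x Numeric series with at least two distinct values.
#' @return The standardised series; a constant series yields all zeros with a
#'   warning.
#' @export
zscore <- function(x) {
  m <- mean(x)
  s <- pop_sd(x)
  if (s == 0) {
    warning("constant series: variance undefined, returning zeros")
    return(numeric(length(x)))
  }
  (x - m) / s
}
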