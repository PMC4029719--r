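#' Butterworth filter specification
#'
#' Describes a causal digital Butterworth filter obtained from the analog
#' prototype by bilinear transform with frequency pre-warping, so that the
#' magnitude response at `cutoff_hz` is exactly -3 dB.
#'
#' @param kind `"high_pass"` or `"low_pass"`.
#' @param cutoff_hz Cutoff (-3 dB) frequency in Hz. Must lie strictly
#'   between 0 and the Nyquist frequency `fs_hz / 2`.
#' @param fs_hz Sampling rate in Hz.
#' @param order Filter order (default 4).
#' @return An object of class `filter_spec` with the design parameters and
#'   the transfer-function coefficients `b` (numerator) and `a`
#'   (denominator, `a[1] == 1`).
#' @examples
#' spec <- filter_spec("high_pass", cutoff_hz = 50, fs_hz = 1024)
#' @export
filter_spec <- function(kind = c("high_pass", "low_pass"), cutoff_hz, fs_hz,
                        order = 4L) {
  kind <- match.arg(kind)
  if (!is.numeric(order) || length(order) != 1L || order < 1)
    stop("invalid configuration: `order` must be a positive integer")
  order <- as.integer(order)
  if (!is.numeric(cutoff_hz) || length(cutoff_hz) != 1L ||
      !is.numeric(fs_hz) || length(fs_hz) != 1L || fs_hz <= 0)
    stop("invalid configuration: cutoff_hz and fs_hz must be positive scalars")
  if (cutoff_hz <= 0 || cutoff_hz >= fs_hz / 2)
    stop("invalid configuration: cutoff_hz must lie in (0, fs_hz/2); got ",
         cutoff_hz, " Hz at fs ", fs_hz, " Hz")
  coefs <- butter_coefficients(order, cutoff_hz, fs_hz, kind)
  structure(list(kind = kind, order = order, cutoff_hz = cutoff_hz,
                 fs_hz = fs_hz, b = coefs$b, a = coefs$a),
            class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf("Butterworth %s filter: order %d, cutoff %g Hz, fs %g Hz\n",
              x$kind, x$order, x$cutoff_hz, x$fs_hz))
  invisible(x)
}

# Polynomial (descending powers) with the given roots; real part taken after
# pairing conjugate roots, valid because designs below use conjugate sets.
poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (rt in r) p <- c(p, 0) - c(0, p) * rt
  p
}

# Digital Butterworth coefficients via analog prototype + bilinear transform.
# Analog low-pass prototype poles lie on the unit circle in the left half
# plane; low-pass scales them by the pre-warped cutoff, high-pass maps
# s -> wc/s (poles wc/p, order zeros at s = 0).
butter_coefficients <- function(order, cutoff_hz, fs_hz, kind) {
  k <- seq_len(order)
  proto <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  wc <- 2 * fs_hz * tan(pi * cutoff_hz / fs_hz)   # pre-warped analog cutoff
  if (kind == "low_pass") {
    poles <- wc * proto
    zeros <- complex(0)
    gain <- wc^order
  } else {
    poles <- wc / proto
    zeros <- rep(0 + 0i, order)
    gain <- 1
  }
  fs2 <- 2 * fs_hz
  zp <- (fs2 + poles) / (fs2 - poles)
  zz <- (fs2 + zeros) / (fs2 - zeros)
  gain_d <- gain * Re(prod(fs2 - zeros) / prod(fs2 - poles))
  zz <- c(zz, rep(-1 + 0i, order - length(zeros)))  # zeros at Nyquist fill
  b <- gain_d * Re(poly_from_roots(zz))
  a <- Re(poly_from_roots(zp))
  list(b = b / a[1], a = a / a[1])
}

#' Apply a causal Butterworth filter
#'
#' Forward-only (causal) IIR filtering with zero initial conditions: sample
#' `n` of the output depends only on input samples `1..n`. Causality is
#' required by the streaming controller; the offline pipeline uses the same
#' chain so that training and deployment see identical features.
#'
#' @param signal Numeric vector (one channel).
#' @param spec A [filter_spec()].
#' @return Filtered vector of the same length.
#' @examples
#' lp <- filter_spec("low_pass", 10, 1024)
#' y <- butterworth_filter(rep(1, 2048), lp)  # settles to 1 (unit DC gain)
#' @export
butterworth_filter <- function(signal, spec) {
  if (!inherits(spec, "filter_spec")) stop("`spec` must be a filter_spec")
  if (!is.numeric(signal)) stop("`signal` must be numeric")
  if (length(signal) <= 3L * spec$order)
    stop("signal too short for order-", spec$order, " filtering")
  if (anyNA(signal) || any(!is.finite(signal)))
    stop("`signal` must be finite")
  iir_filter(signal, spec$b, spec$a)
}

# Direct-form transposed-free IIR: MA part by zero-padded convolution,
# AR part by stats::filter recursion (both C-backed).
iir_filter <- function(x, b, a) {
  n <- length(x)
  xp <- c(rep(0, length(b) - 1L), x)
  v <- stats::filter(xp, b, method = "convolution", sides = 1)
  v <- as.numeric(v)[length(b):(length(b) + n - 1L)]
  if (length(a) > 1L) {
    y <- stats::filter(v, -a[-1L], method = "recursive")
    as.numeric(y)
  } else v
}

# Complex frequency response of a filter_spec at frequencies f_hz.
# Used by tests and the methods vignette; exported for transparency.

#' Frequency response of a designed filter
#'
#' Evaluates the digital transfer function \eqn{H(e^{-i 2\pi f/f_s})} of a
#' [filter_spec()] at the requested frequencies.
#'
#' @param spec A [filter_spec()].
#' @param f_hz Numeric vector of frequencies in Hz.
#' @return Complex vector of responses; take `Mod()` for magnitude.
#' @export
filter_response <- function(spec, f_hz) {
  w <- 2 * pi * f_hz / spec$fs_hz
  z <- exp(-1i * outer(w, seq_along(spec$b) - 1))
  num <- drop(z %*% spec$b)
  zd <- exp(-1i * outer(w, seq_along(spec$a) - 1))
  den <- drop(zd %*% spec$a)
  num / den
}
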