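#' Overlapped analysis-window specification
#'
#' A 200 ms window keeps the feature-plus-classification latency of the
#' real-time loop under the 300 ms budget a wearer perceives as immediate.
#' The default 50 ms step (75% overlap) means a fresh command is available
#' every 50 ms; the overlap/step is configurable.
#'
#' @param length_ms Window length in milliseconds (default 200).
#' @param step_ms Hop between successive window starts (default 50). Must
#'   satisfy `0 < step_ms <= length_ms`.
#' @param fs_hz Sampling rate in Hz.
#' @return A `window_spec` with derived `length_samples` and `step_samples`
#'   (millisecond values floored to whole samples).
#' @export
window_spec <- function(length_ms = 200, step_ms = 50, fs_hz = 1024) {
  if (!is.numeric(length_ms) || length_ms <= 0 ||
      !is.numeric(step_ms) || step_ms <= 0 || step_ms > length_ms)
    stop("invalid configuration: need 0 < step_ms <= length_ms")
  ls <- floor(length_ms * fs_hz / 1000)
  ss <- floor(step_ms * fs_hz / 1000)
  if (ls < 1L || ss < 1L)
    stop("invalid configuration: window or step shorter than one sample")
  structure(list(length_ms = length_ms, step_ms = step_ms, fs_hz = fs_hz,
                 length_samples = as.integer(ls),
                 step_samples = as.integer(ss)),
            class = "window_spec")
}

#' Full-wave rectification
#'
#' @param signal Numeric vector or matrix.
#' @return Elementwise absolute value.
#' @export
rectify <- function(signal) abs(signal)

#' Condition a recording into per-muscle EMG envelopes
#'
#' The per-channel chain is: causal 4th-order Butterworth high-pass at
#' 50 Hz (removes motion artifact and baseline), full-wave rectification,
#' causal 4th-order Butterworth low-pass at 10 Hz (amplitude envelope).
#' Filters start from zero state, so roughly the first three low-pass time
#' constants (~0.05 s) of each trial carry a startup transient.
#'
#' @param recording An `emg_recording` (see [generate_trial()]), or a
#'   numeric matrix with channels in rows plus `fs_hz`.
#' @param fs_hz Sampling rate, only needed when `recording` is a bare
#'   matrix.
#' @param hp_cutoff_hz,lp_cutoff_hz,order Filter chain parameters
#'   (defaults 50 Hz, 10 Hz, order 4).
#' @return Matrix of the same shape as the EMG input: conditioned envelope
#'   per channel.
#' @export
preprocess <- function(recording, fs_hz = NULL, hp_cutoff_hz = 50,
                       lp_cutoff_hz = 10, order = 4L) {
  if (inherits(recording, "emg_recording")) {
    emg <- recording$emg_uV
    fs_hz <- recording$fs_hz
  } else {
    emg <- as.matrix(recording)
    if (is.null(fs_hz)) stop("fs_hz required for a bare matrix")
  }
  hp <- filter_spec("high_pass", hp_cutoff_hz, fs_hz, order)
  lp <- filter_spec("low_pass", lp_cutoff_hz, fs_hz, order)
  out <- emg
  for (ch in seq_len(nrow(emg)))
    out[ch, ] <- butterworth_filter(rectify(butterworth_filter(emg[ch, ], hp)), lp)
  out
}

#' Overlapped-window RMS features
#'
#' For each window position the root mean square
#' \eqn{\sqrt{(1/N) \sum_{i=1}^{N} v_i^2}} is computed per channel; windows
#' advance by `step_samples` and a trailing partial window is dropped
#' rather than padded (no fabricated samples in the real-time semantic).
#'
#' @param conditioned Numeric vector (one channel) or matrix with channels
#'   in rows.
#' @param window A [window_spec()].
#' @return A `feature_frame`: list with `rms_uV` (n_windows x n_channels
#'   matrix), `t_end_s` (window-end timestamps, sample index / fs) and
#'   `window`.
#' @examples
#' w <- window_spec(200, 50, 1024)
#' ff <- rms_windows(sin(seq_len(4096)), w)
#' nrow(ff$rms_uV)  # floor((4096 - 204) / 51) + 1 = 77
#' @export
rms_windows <- function(conditioned, window) {
  stopifnot(inherits(window, "window_spec"))
  x <- if (is.matrix(conditioned)) conditioned else
    matrix(conditioned, nrow = 1L)
  n <- ncol(x)
  ls <- window$length_samples
  ss <- window$step_samples
  if (n < ls)
    stop("empty features: trace (", n, " samples) shorter than one window (",
         ls, " samples)")
  n_win <- (n - ls) %/% ss + 1L
  starts <- 1L + (seq_len(n_win) - 1L) * ss
  ends <- starts + ls - 1L
  x2 <- x^2
  # cumulative sums give O(n) window sums per channel
  rms <- vapply(seq_len(nrow(x)), function(ch) {
    cs <- c(0, cumsum(x2[ch, ]))
    sqrt((cs[ends + 1L] - cs[starts]) / ls)
  }, numeric(n_win))
  rms <- matrix(rms, nrow = n_win,
                dimnames = list(NULL, rownames(x)))
  structure(list(rms_uV = rms, t_end_s = ends / window$fs_hz,
                 end_samples = ends, window = window),
            class = "feature_frame")
}

#' @export
print.feature_frame <- function(x, ...) {
  cat(sprintf("feature_frame: %d windows x %d channels (%g ms window, %g ms step)\n",
              nrow(x$rms_uV), ncol(x$rms_uV), x$window$length_ms,
              x$window$step_ms))
  invisible(x)
}

#' Number of complete analysis windows in a trace
#'
#' @param n_samples Trace length in samples.
#' @param window A [window_spec()].
#' @return `floor((n_samples - length_samples) / step_samples) + 1`, or 0
#'   for traces shorter than one window.
#' @export
n_windows <- function(n_samples, window) {
  if (n_samples < window$length_samples) return(0L)
  as.integer((n_samples - window$length_samples) %/% window$step_samples + 1L)
}
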