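#' Remove the gravity component from a recording
#'
#' The accelerometer reports device motion superimposed on the constant
#' acceleration due to gravity. Gravity is isolated per channel with an
#' exponentially weighted low-pass filter,
#' `g[n] = alpha * g[n-1] + (1 - alpha) * a[n]` with `g[1] = a[1]`, and
#' subtracted to leave the linear acceleration. An abrupt motion peak moves
#' the slowly tracking mean only a little, so the estimate follows the
#' orientation-dependent gravity baseline rather than the activity signal.
#'
#' @param rec an [accel_recording()].
#' @param alpha smoothing weight in `[0, 1)`. Larger values track gravity more
#'   slowly. Default 0.8, a standard exponential-smoothing constant for
#'   gravity isolation at tens of Hz.
#' @return A recording of linear acceleration, labels preserved.
#' @export
remove_gravity <- function(rec, alpha = 0.8) {
  stopifnot(inherits(rec, "accel_recording"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha >= 1) {
    stop_param("alpha must lie in [0, 1)")
  }
  lp <- function(a) {
    g <- as.numeric(stats::filter((1 - alpha) * a, alpha,
                                  method = "recursive", init = a[1L]))
    a - g
  }
  replace_channels(rec, lp(rec$x), lp(rec$y), lp(rec$z))
}

# Causal moving average of a single series; the first order-1 samples are
# averaged over the available prefix rather than padded.
moving_average <- function(v, order) {
  n <- length(v)
  cs <- cumsum(v)
  idx <- seq_len(n)
  out <- cs / idx
  if (order < n) {
    tail_idx <- (order + 1L):n
    out[tail_idx] <- (cs[tail_idx] - cs[tail_idx - order]) / order
  }
  out
}

#' Smooth a recording with a causal moving-average filter
#'
#' Outlier noise is reduced with a short moving average (default order 3):
#' `y[n] = mean(x[max(1, n-order+1) .. n])`. The causal form keeps the filter
#' usable in a streaming, real-time setting; the first `order - 1` samples are
#' averaged over the shorter prefix available.
#'
#' @param rec an [accel_recording()].
#' @param order filter length in samples, `1 <= order <= length(rec)`.
#' @return The smoothed recording (same length, labels preserved).
#' @export
smooth_recording <- function(rec, order = 3) {
  stopifnot(inherits(rec, "accel_recording"))
  if (!is.numeric(order) || length(order) != 1L || order < 1) {
    stop_param("order must be >= 1")
  }
  order <- as.integer(order)
  if (order > length(rec$time)) stop_param("order exceeds the signal length")
  replace_channels(rec,
                   moving_average(rec$x, order),
                   moving_average(rec$y, order),
                   moving_average(rec$z, order))
}

#' Construct a signal window
#'
#' @param samples numeric N x 3 matrix (columns x, y, z) of linear
#'   acceleration.
#' @param sampling_rate Hz.
#' @param window_seconds window duration in seconds;
#'   `nrow(samples) == round(window_seconds * sampling_rate)`.
#' @param activity,position,subject labels inherited from the parent
#'   recording.
#' @return An object of class `signal_window`.
#' @export
signal_window <- function(samples, sampling_rate, window_seconds,
                          activity = NULL, position = NULL, subject = NULL) {
  samples <- as.matrix(samples)
  if (ncol(samples) != 3L) stop_data("a signal window has exactly 3 channels")
  if (anyNA(samples)) stop_data("signal window contains missing values")
  if (nrow(samples) != round(window_seconds * sampling_rate)) {
    stop_data("window length inconsistent with window_seconds * sampling_rate")
  }
  colnames(samples) <- c("x", "y", "z")
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 window_seconds = window_seconds, activity = activity,
                 position = position, subject = subject),
            class = "signal_window")
}

#' @export
print.signal_window <- function(x, ...) {
  cat(sprintf("<signal_window> %d x 3 samples (%.3g s @ %.4g Hz)%s\n",
              nrow(x$samples), x$window_seconds, x$sampling_rate,
              if (is.null(x$activity)) "" else paste0(" [", x$activity, "]")))
  invisible(x)
}

#' Segment a recording into fixed-length windows
#'
#' Splits a recording into windows of `window_seconds` (default 3 s, i.e. 60
#' samples per axis at 20 Hz), the unit of feature extraction and
#' classification. Windows are non-overlapping by default; the step is
#' `round(N_window * (1 - overlap_fraction))`. A trailing partial window is
#' discarded. A recording shorter than one window yields an empty list.
#'
#' @param rec an [accel_recording()].
#' @param window_seconds window duration in seconds.
#' @param overlap_fraction fraction of each window shared with the next, in
#'   `[0, 1)`.
#' @return A list of [signal_window()] objects carrying the parent labels.
#' @export
segment_recording <- function(rec, window_seconds = 3, overlap_fraction = 0) {
  stopifnot(inherits(rec, "accel_recording"))
  if (overlap_fraction < 0 || overlap_fraction >= 1) {
    stop_param("overlap_fraction must lie in [0, 1)")
  }
  if (window_seconds <= 0) stop_param("window_seconds must be positive")
  nw <- as.integer(round(window_seconds * rec$sampling_rate))
  n <- length(rec$time)
  if (nw < 1L || n < nw) return(list())
  step <- max(1L, as.integer(round(nw * (1 - overlap_fraction))))
  starts <- seq.int(1L, n - nw + 1L, by = step)
  mat <- cbind(x = rec$x, y = rec$y, z = rec$z)
  lapply(starts, function(s) {
    signal_window(mat[s:(s + nw - 1L), , drop = FALSE], rec$sampling_rate,
                  window_seconds, activity = rec$activity,
                  position = rec$position, subject = rec$subject)
  })
}
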