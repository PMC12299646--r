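#' Uniformly sampled time series
#'
#' Lightweight container for one channel of uniformly sampled data: a numeric
#' vector plus its sampling rate, units and label. All signal-processing and
#' segmentation functions in the package operate on this class.
#'
#' @param samples Numeric vector of samples (finite).
#' @param rate Sampling rate in Hz (> 0).
#' @param units Unit string, e.g. `"deg"`, `"m/s^2"`, `"%SVIC"`.
#' @param label Channel label.
#' @return An object of class `scap_ts`.
#' @export
#' @examples
#' x <- time_series(sin(seq(0, 2 * pi, length.out = 101)), rate = 100, units = "deg")
#' ts_duration(x)
time_series <- function(samples, rate, units = "", label = "") {
  samples <- as.numeric(samples)
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0) {
    stop("`rate` must be a single positive number (Hz)", call. = FALSE)
  }
  if (length(samples) == 0L) stop("`samples` must be non-empty", call. = FALSE)
  if (anyNA(samples) || any(!is.finite(samples))) {
    stop("`samples` must be finite", call. = FALSE)
  }
  structure(
    list(samples = samples, rate = rate, units = units, label = label),
    class = "scap_ts"
  )
}

#' @export
print.scap_ts <- function(x, ...) {
  cat(sprintf(
    "<scap_ts> %s: %d samples @ %g Hz (%.3f s)%s\n",
    if (nzchar(x$label)) x$label else "unnamed",
    length(x$samples), x$rate, ts_duration(x),
    if (nzchar(x$units)) paste0(" [", x$units, "]") else ""
  ))
  invisible(x)
}

#' Time stamps of a time series
#'
#' @param x A `scap_ts`. Sample `i` is stamped `(i - 1) / rate`, so recordings
#'   start at `t = 0`.
#' @return Numeric vector of times in seconds.
#' @export
ts_times <- function(x) {
  stopifnot(inherits(x, "scap_ts"))
  (seq_along(x$samples) - 1) / x$rate
}

#' Duration of a time series in seconds
#' @param x A `scap_ts`.
#' @return Duration `(n - 1) / rate` in seconds.
#' @export
ts_duration <- function(x) {
  stopifnot(inherits(x, "scap_ts"))
  (length(x$samples) - 1) / x$rate
}

#' Sample indices covered by a time window
#'
#' Maps a half-open time window `[t0, t1)` onto sample indices of a series.
#' The window convention is shared by the synthetic generator's ground truth
#' and by the per-phase metrics, so that both sides select identical samples.
#'
#' @param x A `scap_ts`.
#' @param window Numeric length-2, `c(t0, t1)` in seconds, `t0 < t1`.
#' @param closed_end Include the sample lying exactly at `t1` (used for the
#'   final phase so the task end sample belongs to the last phase).
#' @return Integer vector of indices.
#' @export
window_indices <- function(x, window, closed_end = FALSE) {
  stopifnot(inherits(x, "scap_ts"), length(window) == 2L)
  if (!all(is.finite(window)) || window[2] <= window[1]) {
    stop("`window` must be finite with t0 < t1", call. = FALSE)
  }
  # tolerant rounding so that grid-aligned boundaries pick up their own sample
  i0 <- ceiling(window[1] * x$rate - 1e-9) + 1L
  i1 <- if (closed_end) {
    floor(window[2] * x$rate + 1e-9) + 1L
  } else {
    ceiling(window[2] * x$rate - 1e-9) # last index strictly before t1
  }
  i0 <- max(1L, as.integer(i0))
  i1 <- min(length(x$samples), as.integer(i1))
  if (i1 < i0) stop("empty window: no samples in [t0, t1)", call. = FALSE)
  seq.int(i0, i1)
}

#' Extract a sub-series over a time window
#' @inheritParams window_indices
#' @return A `scap_ts` holding the windowed samples (time re-zeroed).
#' @export
ts_window <- function(x, window, closed_end = FALSE) {
  idx <- window_indices(x, window, closed_end = closed_end)
  time_series(x$samples[idx], x$rate, x$units, x$label)
}

#' Block-mean downsampling to a divisor rate
#'
#' Reduces a high-rate series (e.g. a 2000 Hz EMG envelope) to a lower rate
#' whose ratio is an integer (e.g. 100 Hz) by averaging consecutive blocks.
#' Sample `k` of the output is the mean of input samples
#' `((k-1)*f + 1) : (k*f)` with `f = rate_in / rate_out`.
#'
#' @param x A `scap_ts`.
#' @param rate_out Target rate; `x$rate` must be an integer multiple of it.
#' @return A `scap_ts` at `rate_out`.
#' @export
downsample_block_mean <- function(x, rate_out) {
  stopifnot(inherits(x, "scap_ts"))
  f <- x$rate / rate_out
  if (abs(f - round(f)) > 1e-9 || f < 1) {
    stop("input rate must be an integer multiple of `rate_out`", call. = FALSE)
  }
  f <- as.integer(round(f))
  n_out <- length(x$samples) %/% f
  if (n_out < 1L) stop("series shorter than one output block", call. = FALSE)
  y <- colMeans(matrix(x$samples[seq_len(n_out * f)], nrow = f))
  time_series(y, rate_out, x$units, x$label)
}

# internal: first central difference at the sampling rate (endpoints one-sided)
ts_gradient <- function(v, rate) {
  n <- length(v)
  if (n < 3L) stop("need at least 3 samples to differentiate", call. = FALSE)
  g <- numeric(n)
  g[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) * rate / 2
  g[1] <- (v[2] - v[1]) * rate
  g[n] <- (v[n] - v[n - 1]) * rate
  g
}

# internal: trapezoidal integral of y sampled at `rate`
ts_trapz <- function(y, rate) {
  n <- length(y)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) / 2) / rate
}
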