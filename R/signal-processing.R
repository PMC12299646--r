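#' Band-pass filter raw surface EMG
#'
#' 2nd-order Butterworth band-pass (20--450 Hz) applied zero-phase
#' (forward-backward), the standard conditioning step before envelope
#' extraction. Zero-phase application preserves the timing of bursts relative
#' to the kinematic events used for segmentation; the effective attenuation
#' order doubles.
#'
#' @param raw A `scap_ts` of raw EMG. The sampling rate must exceed 1000 Hz so
#'   the 450 Hz passband edge stays below Nyquist with margin.
#' @param band Passband edges in Hz, default `c(20, 450)`.
#' @param order Butterworth order of the analogue prototype (default 2).
#' @return A `scap_ts` of identical length and rate.
#' @export
bandpass_emg <- function(raw, band = c(20, 450), order = 2) {
  stopifnot(inherits(raw, "scap_ts"))
  if (raw$rate <= 900) {
    stop("EMG sampling rate must exceed 900 Hz for a 20-450 Hz passband", call. = FALSE)
  }
  bf <- signal::butter(order, band / (raw$rate / 2), type = "pass")
  time_series(signal::filtfilt(bf, raw$samples), raw$rate, raw$units, raw$label)
}

#' Low-pass filter hand acceleration
#'
#' 4th-order Butterworth low-pass at 4 Hz, zero-phase, used on the hand
#' accelerometer channel before onset/offset detection and velocity
#' integration.
#'
#' @param raw A `scap_ts` of acceleration (m/s^2).
#' @param cutoff Cutoff frequency in Hz (default 4).
#' @param order Filter order (default 4).
#' @return A `scap_ts` of identical length and rate.
#' @export
lowpass_accel <- function(raw, cutoff = 4, order = 4) {
  stopifnot(inherits(raw, "scap_ts"))
  if (raw$rate <= 2 * cutoff) {
    stop("sampling rate must exceed twice the cutoff frequency", call. = FALSE)
  }
  bf <- signal::butter(order, cutoff / (raw$rate / 2), type = "low")
  time_series(signal::filtfilt(bf, raw$samples), raw$rate, raw$units, raw$label)
}

#' Sliding-window RMS envelope
#'
#' Root-mean-square over a sliding window of `window` samples (default 100,
#' i.e. 50 ms at 2000 Hz). The output is same-length and centre-aligned:
#' sample `i` summarizes input samples `i - floor((w-1)/2)` through
#' `i + ceiling((w-1)/2)`, with reflective padding at the edges so the EMG
#' envelope stays alignable with the kinematic time base.
#'
#' @param filtered A `scap_ts` (typically band-passed EMG).
#' @param window Window length in samples (>= 1, <= series length).
#' @return A non-negative `scap_ts` of identical length and rate.
#' @export
rms_envelope <- function(filtered, window = 100) {
  stopifnot(inherits(filtered, "scap_ts"))
  n <- length(filtered$samples)
  window <- as.integer(window)
  if (window < 1L) stop("`window` must be >= 1 sample", call. = FALSE)
  if (window > n) stop("`window` exceeds the series length", call. = FALSE)
  x2 <- filtered$samples^2
  hl <- (window - 1L) %/% 2L  # samples taken to the left of centre
  hr <- window - 1L - hl
  pad_l <- if (hl > 0L) x2[hl:1] else numeric(0)
  pad_r <- if (hr > 0L) x2[n:(n - hr + 1L)] else numeric(0)
  xp <- c(pad_l, x2, pad_r)
  cs <- cumsum(c(0, xp))
  ms <- (cs[(window + 1L):(window + n)] - cs[1:n]) / window
  time_series(sqrt(pmax(ms, 0)), filtered$rate, filtered$units,
              paste0(filtered$label, "_rms"))
}

#' SVIC normalization reference for one muscle
#'
#' Computes the submaximal voluntary isometric contraction (SVIC) reference
#' amplitude from three 5-s repetitions: the mean, over repetitions, of the
#' mean RMS envelope of each repetition's central portion (default central
#' 3 s, discarding ramp-up and ramp-down).
#'
#' @param svic A `scap_svic` object (see [generate_svic()]) or a plain list
#'   with elements `muscle` and `repetitions` (a list of three `scap_ts`
#'   envelopes). If a repetition carries attribute `raw = TRUE` it is first
#'   band-passed and RMS-enveloped.
#' @param central_s Central window retained from each repetition (s).
#' @param rms_window RMS window in samples for raw repetitions.
#' @return Reference amplitude (same units as the envelopes), a single
#'   positive number.
#' @export
svic_reference <- function(svic, central_s = 3, rms_window = 100) {
  reps <- svic$repetitions
  if (length(reps) != 3L) stop("SVIC recording must hold exactly 3 repetitions", call. = FALSE)
  rep_means <- vapply(reps, function(r) {
    stopifnot(inherits(r, "scap_ts"))
    if (isTRUE(attr(r, "raw"))) r <- rms_envelope(bandpass_emg(r), rms_window)
    dur <- ts_duration(r)
    if (dur < central_s) stop("SVIC repetition shorter than the central window", call. = FALSE)
    t0 <- (dur - central_s) / 2
    mean(ts_window(r, c(t0, t0 + central_s), closed_end = TRUE)$samples)
  }, numeric(1))
  ref <- mean(rep_means)
  if (!is.finite(ref) || ref < sqrt(.Machine$double.eps)) {
    stop("degenerate SVIC reference (~0); cannot normalize", call. = FALSE)
  }
  ref
}

#' Normalize an EMG envelope to %SVIC
#'
#' @param envelope A `scap_ts` amplitude envelope.
#' @param reference Positive SVIC reference amplitude in the same units.
#' @return A `scap_ts` in percent of the SVIC reference.
#' @export
normalize_to_svic <- function(envelope, reference) {
  stopifnot(inherits(envelope, "scap_ts"))
  if (!is.finite(reference) || reference <= 0) {
    stop("`reference` must be a positive number", call. = FALSE)
  }
  time_series(envelope$samples * 100 / reference, envelope$rate, "%SVIC",
              envelope$label)
}

#' Rest position of an angle channel
#'
#' Arithmetic mean of the first `rest_window` seconds of a static recording
#' (samples at `t = 0` through `t = rest_window` inclusive), used as the
#' joint's neutral/rest reference.
#'
#' @param angle A `scap_ts` of joint angle (deg) covering at least
#'   `rest_window` seconds.
#' @param rest_window Averaging window from the start of the recording (s).
#' @return Mean angle in degrees.
#' @export
rest_position <- function(angle, rest_window = 5) {
  stopifnot(inherits(angle, "scap_ts"))
  if (ts_duration(angle) < rest_window) {
    stop(sprintf("recording covers %.2f s; need >= %g s of static data",
                 ts_duration(angle), rest_window), call. = FALSE)
  }
  mean(ts_window(angle, c(0, rest_window), closed_end = TRUE)$samples)
}
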