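# Task onset/offset detection from hand acceleration and kinematic phase
# segmentation of the five-phase drinking task.
#
# Event definitions: onset/end where the hand acceleration leaves/re-enters
# a +-0.3 m/s^2 band around the resting mean; b1 = maximum elbow extension
# before the drink; b2 = initiation of shoulder elevation; b3 = maximum
# shoulder elevation; b4 = next elbow-extension maximum after b3.

#' Segmentation tuning parameters
#'
#' Sustain windows suppress single-sample threshold crossings (the event
#' definitions themselves only state thresholds); the velocity threshold
#' operationalizes "initiation of shoulder elevation"; `event_smooth_hz`
#' low-pass filters angle channels before event detection on noisy data.
#' Refinement walks a detected threshold crossing back to the pre-movement
#' floor so that the reported time is the movement start, not the (biased)
#' crossing; it operates on the raw signal whenever the rest-segment noise
#' estimate is negligible, and on the smoothed signal otherwise.
#'
#' @param accel_threshold Onset/end band half-width, m/s^2 (0.3).
#' @param sustain_onset,sustain_end,sustain_elev Sustain windows in seconds
#'   for onset (0.05), end (0.2) and shoulder-elevation initiation (0.1).
#' @param v_threshold Shoulder elevation velocity threshold, deg/s (5).
#' @param event_smooth_hz Zero-phase Butterworth cutoff (4th order) applied
#'   to angle channels before event detection when they carry noise.
#' @param init_smooth_hz Milder cutoff used only for the elevation-initiation
#'   walk-back, where heavy smoothing would smear the onset backwards.
#' @param refine Walk detected crossings back to the movement start and
#'   refine angle extrema by local quadratic interpolation (noisy data).
#' @param clean_noise_floor Rest-segment noise SD below which a channel is
#'   treated as noise-free (no smoothing, exact sample-resolution events).
#' @return A list of class `scap_seg_params`.
#' @export
segmentation_params <- function(accel_threshold = 0.3,
                                sustain_onset = 0.05,
                                sustain_end = 0.2,
                                sustain_elev = 0.1,
                                v_threshold = 5,
                                event_smooth_hz = 3,
                                init_smooth_hz = 8,
                                refine = TRUE,
                                clean_noise_floor = 1e-7) {
  structure(list(accel_threshold = accel_threshold,
                 sustain_onset = sustain_onset, sustain_end = sustain_end,
                 sustain_elev = sustain_elev, v_threshold = v_threshold,
                 event_smooth_hz = event_smooth_hz,
                 init_smooth_hz = init_smooth_hz, refine = refine,
                 clean_noise_floor = clean_noise_floor),
            class = "scap_seg_params")
}

# robust noise SD from successive differences over a sample index range
noise_sd_est <- function(x, idx) {
  d <- diff(x[idx])
  stats::sd(d) / sqrt(2)
}

# first index at which `cond` holds for `len` consecutive samples
first_sustained <- function(cond, len) {
  r <- rle(cond)
  ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= len)
  if (!length(hit)) return(NA_integer_)
  as.integer(ends[hit[1]] - r$lengths[hit[1]] + 1L)
}

#' Detect task onset from hand acceleration
#'
#' Earliest time at which the absolute deviation of the (low-pass filtered)
#' hand acceleration from its resting mean exceeds `accel_threshold`,
#' sustained for `sustain_onset` seconds. The resting mean is taken over the
#' first `rest_window` seconds.
#'
#' @param accel A `scap_ts` of hand acceleration (already low-pass filtered;
#'   see [lowpass_accel()]).
#' @param rest_window Rest segment used for the resting mean, s (>= 1).
#' @param params A [segmentation_params()].
#' @param refine If `TRUE`, walk the crossing back to the movement start
#'   (where the deviation falls to the rest noise floor). Default `FALSE`:
#'   the threshold-crossing time itself is returned.
#' @param refine_series Optional `scap_ts` on which the walk-back operates
#'   (same rate/length as `accel`); [segment_phases()] passes the unfiltered
#'   acceleration here when it is noise-free, because zero-phase low-pass
#'   smear would otherwise leak before the true movement start.
#' @return Onset time in seconds.
#' @export
detect_onset <- function(accel, rest_window = 5, params = segmentation_params(),
                         refine = FALSE, refine_series = NULL) {
  stopifnot(inherits(accel, "scap_ts"))
  if (rest_window < 1) stop("`rest_window` must cover >= 1 s", call. = FALSE)
  n_rest <- round(rest_window * accel$rate)
  if (n_rest >= length(accel$samples)) stop("rest window exceeds the recording", call. = FALSE)
  rest_mean <- mean(accel$samples[seq_len(n_rest)])
  dev <- abs(accel$samples - rest_mean)
  len <- max(1L, round(params$sustain_onset * accel$rate))
  i <- first_sustained(dev > params$accel_threshold, len)
  if (is.na(i)) stop("no onset: acceleration never leaves the rest band", call. = FALSE)
  if (refine) {
    # locate the movement start: the last sample still at the rest noise
    # floor adjacent to the sustained rise. The crossing may sit late (slow
    # build-up) or early (anti-causal smear of zero-phase filtering), so
    # walk back out of supra-floor territory, then forward through any
    # sub-floor gap up to the rise.
    r <- if (is.null(refine_series)) accel else refine_series
    dev_r <- abs(r$samples - mean(r$samples[seq_len(n_rest)]))
    floor_dev <- max(3 * stats::sd(dev_r[seq_len(n_rest)]), 1e-9)
    n <- length(dev_r)
    while (i > 1L && dev_r[i] > floor_dev) i <- i - 1L
    while (i < n && dev_r[i + 1L] <= floor_dev) i <- i + 1L
  }
  (i - 1) / accel$rate
}

#' Detect task end from hand acceleration
#'
#' Earliest time after `after` at which the deviation from the resting mean
#' returns within the band and stays there for `sustain_end` seconds.
#'
#' @inheritParams detect_onset
#' @param after Time (s) after which to search (the b4 boundary).
#' @param rest_mean Optional precomputed resting mean; defaults to the mean
#'   over the first `rest_window` seconds.
#' @param refine If `TRUE`, advance from the band re-entry to the sample
#'   where the deviation reaches the rest noise floor (movement stop).
#' @param refine_series As in [detect_onset()].
#' @return End time in seconds.
#' @export
detect_end <- function(accel, after, rest_mean = NULL, rest_window = 5,
                       params = segmentation_params(), refine = FALSE,
                       refine_series = NULL) {
  stopifnot(inherits(accel, "scap_ts"))
  n_rest <- round(rest_window * accel$rate)
  if (is.null(rest_mean)) rest_mean <- mean(accel$samples[seq_len(n_rest)])
  dev <- abs(accel$samples - rest_mean)
  i0 <- min(length(dev), round(after * accel$rate) + 2L)
  len <- max(1L, round(params$sustain_end * accel$rate))
  i_rel <- first_sustained(dev[i0:length(dev)] <= params$accel_threshold, len)
  if (is.na(i_rel)) stop("no end: acceleration never returns to the rest band", call. = FALSE)
  i <- i0 + i_rel - 1L
  if (refine) {
    # movement stop: first at-floor sample after the movement, reached by
    # advancing out of supra-floor territory and then retreating through
    # any sub-floor gap (mirror image of the onset refinement)
    r <- if (is.null(refine_series)) accel else refine_series
    dev_r <- abs(r$samples - mean(r$samples[seq_len(n_rest)]))
    floor_dev <- max(3 * stats::sd(dev_r[seq_len(n_rest)]), 1e-9)
    n <- length(dev_r)
    while (i < n && dev_r[i] > floor_dev) i <- i + 1L
    while (i > 1L && dev_r[i - 1L] <= floor_dev) i <- i - 1L
  }
  (i - 1) / accel$rate
}

# argmax over an index window; on noisy data the extremum is refined by a
# least-squares quadratic fitted over +-half_w seconds around the argmax
# (the vertex estimator averages the noise instead of chasing it on the
# flat top of a smooth peak); the vertex is clamped to the fit window
window_argmax <- function(x, idx, rate, refine_cont, half_w = 0.15) {
  i <- idx[which.max(x[idx])]
  t <- (i - 1) / rate
  if (!refine_cont) return(t)
  h <- round(half_w * rate)
  lo <- max(idx[1], i - h); hi <- min(idx[length(idx)], i + h)
  if (hi - lo < 4L) return(t)
  u <- ((lo:hi) - i) / rate
  fit <- stats::lm.fit(cbind(1, u, u^2), x[lo:hi])
  b <- fit$coefficients
  if (!is.finite(b[3]) || b[3] >= 0) return(t)
  vert <- -b[2] / (2 * b[3])
  t + max(-half_w, min(half_w, vert))
}

#' Segment a processed trial into the five task phases
#'
#' Applies the full event chain: acceleration-based onset, elbow-extension
#' maximum (b1), shoulder-elevation initiation (b2), shoulder-elevation
#' maximum (b3), next elbow-extension maximum (b4), acceleration-based end.
#' Angle channels are low-pass filtered before event detection when their
#' rest-segment noise estimate is non-negligible; on noise-free signals the
#' events are recovered exactly at sample resolution.
#'
#' @param trial A `scap_trial` (raw generator output) or `scap_processed`
#'   (see [process_trial()]); the hand acceleration is low-pass filtered here
#'   if it has not been already.
#' @param params A [segmentation_params()].
#' @return A list of class `scap_segmentation` with boundary times (s):
#'   `onset`, `b1`, `b2`, `b3`, `b4`, `end`.
#' @export
segment_phases <- function(trial, params = segmentation_params()) {
  kin <- trial$kin
  accel_raw <- if (!is.null(trial$accel_raw)) trial$accel_raw else trial$accel
  accel <- if (!is.null(trial$accel_filt)) trial$accel_filt else lowpass_accel(accel_raw)
  rest_w <- min(5, trial$rest_duration)
  kr <- kin[[1]]$rate

  # refinement runs on the least-processed acceleration whose rest noise
  # floor stays below the onset band: zero-phase filtering smears movement
  # energy before the true start, which would bias the walk-back, while the
  # raw channel's noise floor merely stops it a few samples late
  acc_rest_idx <- seq_len(round(rest_w * accel$rate))
  refine_on <- if (!is.null(accel_raw) &&
                   3 * stats::sd(accel_raw$samples[acc_rest_idx]) < params$accel_threshold) {
    accel_raw
  } else {
    accel
  }
  onset <- detect_onset(accel, rest_window = rest_w, params = params,
                        refine = params$refine, refine_series = refine_on)

  elbow <- kin$elbow_flexext; shoulder <- kin$shoulder_elev
  if (is.null(elbow) || is.null(shoulder)) {
    stop("trial must carry 'elbow_flexext' and 'shoulder_elev' channels", call. = FALSE)
  }
  rest_idx <- seq_len(round(rest_w * kr))
  noisy <- noise_sd_est(shoulder$samples, rest_idx) > params$clean_noise_floor ||
    noise_sd_est(elbow$samples, rest_idx) > params$clean_noise_floor
  smooth <- function(x) {
    if (!noisy) return(x)
    bf <- signal::butter(4, params$event_smooth_hz / (kr / 2), type = "low")
    as.numeric(signal::filtfilt(bf, x))
  }
  el <- smooth(elbow$samples)
  sh <- smooth(shoulder$samples)
  n <- length(sh)
  i_on <- round(onset * kr) + 1L

  # b3: maximum shoulder elevation after onset
  idx <- (i_on + 1L):n
  b3 <- window_argmax(sh, idx, kr, refine_cont = noisy && params$refine)
  i_b3 <- round(b3 * kr) + 1L
  if (i_b3 <= i_on + 2L) seg_fail("b3", "no shoulder-elevation maximum after onset")

  # b1: global maximum of elbow extension in (onset, b3)
  idx <- (i_on + 1L):(i_b3 - 1L)
  b1 <- window_argmax(el, idx, kr, refine_cont = noisy && params$refine)
  i_b1 <- round(b1 * kr) + 1L
  if (el[i_b1] <= el[i_on] + 1e-9) seg_fail("b1", "elbow extension shows no maximum before the drink")

  # b2: initiation of shoulder elevation in (b1, b3). The sustained
  # threshold crossing of the (smoothed) elevation velocity establishes that
  # an initiation exists; the reported time is then refined by walking back
  # from the velocity peak on a mildly smoothed velocity (heavier smoothing
  # would smear the onset backwards, raw differentiation would drown it in
  # noise) to the last sample at the rest velocity floor.
  v <- ts_gradient(sh, kr)
  search <- (i_b1 + 1L):(i_b3 - 1L)
  len <- max(1L, round(params$sustain_elev * kr))
  i_rel <- first_sustained(v[search] > params$v_threshold, len)
  if (is.na(i_rel)) seg_fail("b2", "shoulder-elevation velocity never exceeds the threshold")
  if (noisy) {
    bf2 <- signal::butter(4, params$init_smooth_hz / (kr / 2), type = "low")
    v_ref <- ts_gradient(as.numeric(signal::filtfilt(bf2, shoulder$samples)), kr)
    v_floor <- max(2 * stats::sd(v_ref[rest_idx[-c(1L, length(rest_idx))]]),
                   params$v_threshold)
  } else {
    v_ref <- ts_gradient(shoulder$samples, kr)
    v_floor <- 0
  }
  i_anchor <- search[which.max(v[search])]
  i <- i_anchor
  while (i > i_b1 + 1L && v_ref[i] > v_floor) i <- i - 1L
  b2 <- (min(i + 1L, i_anchor) - 1) / kr

  # b4: next elbow-extension maximum after b3
  idx <- (i_b3 + 1L):n
  b4 <- window_argmax(el, idx, kr, refine_cont = noisy && params$refine)
  if (el[round(b4 * kr) + 1L] <= el[n] + 1e-9) {
    seg_fail("b4", "no elbow-extension maximum after the drink")
  }

  endt <- detect_end(accel, after = b4, rest_window = rest_w, params = params,
                     refine = params$refine, refine_series = refine_on)

  seg <- list(onset = onset, b1 = b1, b2 = b2, b3 = b3, b4 = b4, end = endt)
  bvals <- unlist(seg)
  if (any(diff(bvals) <= 0)) {
    bad <- names(seg)[which(diff(bvals) <= 0)[1] + 1L]
    seg_fail(bad, "boundaries are not strictly increasing")
  }
  structure(seg, class = "scap_segmentation")
}

seg_fail <- function(boundary, why) {
  stop(sprintf("segmentation failure at %s: %s", boundary, why), call. = FALSE)
}

#' Phase windows of a segmentation
#'
#' @param seg A `scap_segmentation`.
#' @return Data frame with one row per phase: `phase`, `start`, `end` (s).
#'   Windows are half-open `[start, end)` except the last, which includes the
#'   task end sample.
#' @export
phase_windows <- function(seg) {
  stopifnot(inherits(seg, "scap_segmentation"))
  b <- unlist(seg)
  data.frame(phase = scap_phases,
             start = unname(b[1:5]), end = unname(b[2:6]))
}

#' @export
print.scap_segmentation <- function(x, ...) {
  cat("<scap_segmentation>\n")
  print(round(unlist(x), 3))
  invisible(x)
}
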