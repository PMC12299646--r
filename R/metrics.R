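# Per-phase kinematic/EMG metrics and whole-task movement-quality metrics.

#' Range of motion within a time window
#'
#' Angular difference between the maximum and minimum joint position inside
#' the window.
#'
#' @param angle A `scap_ts` of joint angle (deg).
#' @param window `c(t0, t1)` in seconds.
#' @param closed_end Include the sample at `t1` (used for the final phase).
#' @return Non-negative ROM in degrees.
#' @export
range_of_motion <- function(angle, window, closed_end = FALSE) {
  idx <- window_indices(angle, window, closed_end = closed_end)
  max(angle$samples[idx]) - min(angle$samples[idx])
}

#' Scapulohumeral rhythm
#'
#' Ratio of shoulder elevation ROM to scapular upward-rotation ROM over the
#' elevation window (by default the drink phase, where the arm is raised).
#'
#' @param shoulder_elev,scap_ur `scap_ts` channels (deg).
#' @param window `c(t0, t1)` elevation window in seconds.
#' @param min_scap_rom Degeneracy floor for the scapular denominator (deg).
#' @return Dimensionless ratio.
#' @export
scapulohumeral_rhythm <- function(shoulder_elev, scap_ur, window,
                                  min_scap_rom = 0.5) {
  rom_sh <- range_of_motion(shoulder_elev, window)
  rom_ur <- range_of_motion(scap_ur, window)
  if (rom_ur < min_scap_rom) {
    stop(sprintf("degenerate scapular upward-rotation ROM (%.3f deg < %g deg)",
                 rom_ur, min_scap_rom), call. = FALSE)
  }
  rom_sh / rom_ur
}

# core dimensionless-jerk computation on a velocity sample vector.
# speed variant: DJ = D^3 / v_peak^2 * int j^2 dt, j the second derivative
# of velocity; a single minimum-jerk segment gives exactly
# 720 / (15/8)^2 = 204.8. amplitude variant: DJ = D^5 / L^2 * int j^2 dt
# with L the path length int |v| dt.
log_dimensionless_jerk_samples <- function(v, rate, variant = c("speed", "amplitude")) {
  variant <- match.arg(variant)
  n <- length(v)
  if (n < 5L) stop("velocity window too short for jerk estimation", call. = FALSE)
  D <- (n - 1) / rate
  # jerk = second derivative of velocity: central second differences in the
  # interior, second-order one-sided stencils at the endpoints (the jerk of
  # a reaching movement peaks at the segment ends, so edge samples carry
  # real integrand mass and must not be dropped)
  j <- numeric(n)
  j[2:(n - 1)] <- (v[3:n] - 2 * v[2:(n - 1)] + v[1:(n - 2)]) * rate^2
  j[1] <- (2 * v[1] - 5 * v[2] + 4 * v[3] - v[4]) * rate^2
  j[n] <- (2 * v[n] - 5 * v[n - 1] + 4 * v[n - 2] - v[n - 3]) * rate^2
  int_j2 <- ts_trapz(j^2, rate)
  if (variant == "speed") {
    v_peak <- max(abs(v))
    if (v_peak <= 0) stop("zero peak speed in the smoothness window", call. = FALSE)
    dj <- D^3 / v_peak^2 * int_j2
  } else {
    L <- ts_trapz(abs(v), rate)
    if (L <= 0) stop("zero path length in the smoothness window", call. = FALSE)
    dj <- D^5 / L^2 * int_j2
  }
  log(dj)
}

#' Log dimensionless jerk movement smoothness
#'
#' Global movement smoothness from the hand velocity profile over the task
#' window. The default (speed-normalized) variant is
#' \deqn{\ln\!\big(D^3 / v_{peak}^2 \int j(t)^2 dt\big)}
#' with `D` the window duration, `v_peak` the peak speed and `j` the jerk
#' (second time-derivative of velocity, estimated by central differences).
#' Larger values indicate less smooth movement. The value is invariant to
#' uniform time rescaling and to amplitude scaling of the velocity profile;
#' a single minimum-jerk segment yields exactly `ln(204.8) = 5.3220`. The
#' `"amplitude"` variant normalizes by path length squared
#' (\eqn{D^5/L^2 \int j^2}) instead of peak speed.
#'
#' @param hand_velocity A `scap_ts` of (signed) hand velocity, m/s.
#' @param window `c(onset, end)` in seconds; default the whole series.
#' @param variant `"speed"` (default) or `"amplitude"`.
#' @return `ln(DJ)`, dimensionless.
#' @export
log_dimensionless_jerk <- function(hand_velocity, window = NULL,
                                   variant = c("speed", "amplitude")) {
  stopifnot(inherits(hand_velocity, "scap_ts"))
  variant <- match.arg(variant)
  v <- if (is.null(window)) hand_velocity$samples else
    hand_velocity$samples[window_indices(hand_velocity, window, closed_end = TRUE)]
  log_dimensionless_jerk_samples(v, hand_velocity$rate, variant)
}

#' Hand velocity by integration of filtered acceleration
#'
#' Trapezoidal integration of the low-pass-filtered signed hand acceleration
#' over the task window, followed by linear detrending pinned at the window
#' endpoints (the hand is at rest at onset and end), which controls
#' integration drift from sensor bias.
#'
#' @param accel_filt A `scap_ts` of filtered signed acceleration (m/s^2).
#' @param window `c(onset, end)` in seconds.
#' @return A `scap_ts` of velocity (m/s) over the window.
#' @export
hand_velocity <- function(accel_filt, window) {
  stopifnot(inherits(accel_filt, "scap_ts"))
  idx <- window_indices(accel_filt, window, closed_end = TRUE)
  a <- accel_filt$samples[idx]
  dt <- 1 / accel_filt$rate
  v <- c(0, cumsum((a[-1] + a[-length(a)]) / 2 * dt))
  drift <- seq(0, v[length(v)], length.out = length(v))
  time_series(v - drift, accel_filt$rate, "m/s", "hand_velocity")
}

#' Percentage of time to peak acceleration
#'
#' Time of the highest instantaneous absolute hand acceleration within the
#' reaching phase, expressed as a percentage of the whole task duration.
#' Ties resolve to the earliest sample.
#'
#' @param accel A `scap_ts` of hand acceleration.
#' @param reaching `c(t0, t1)` reaching-phase window (s).
#' @param task `c(onset, end)` task window (s).
#' @return Percentage in `[0, 100]`.
#' @export
time_to_peak_percent <- function(accel, reaching, task) {
  stopifnot(inherits(accel, "scap_ts"))
  idx <- window_indices(accel, reaching)
  t_peak <- (idx[argmax_earliest(abs(accel$samples[idx]))] - 1) / accel$rate
  100 * (t_peak - task[1]) / (task[2] - task[1])
}

# earliest index attaining the maximum up to a relative rounding tolerance,
# so symmetric profiles tie-break deterministically to the earlier extremum
argmax_earliest <- function(x, rel_tol = 1e-12) {
  m <- max(x)
  which(x >= m - abs(m) * rel_tol)[1]
}

#' Trunk compensation
#'
#' Signed deviation from the neutral (rest) posture with the largest
#' absolute value inside the window: the peak variation of trunk movement
#' during the task.
#'
#' @param trunk_angle A `scap_ts` of a trunk angle (deg).
#' @param window `c(t0, t1)` in seconds.
#' @param neutral Neutral angle (deg), from [rest_position()].
#' @return Signed peak deviation in degrees.
#' @export
trunk_compensation <- function(trunk_angle, window, neutral) {
  idx <- window_indices(trunk_angle, window, closed_end = TRUE)
  dev <- trunk_angle$samples[idx] - neutral
  dev[which.max(abs(dev))]
}

#' Mean EMG activity level within a phase
#'
#' @param envelope_pct A `scap_ts` EMG envelope in %SVIC (kinematic rate).
#' @param window `c(t0, t1)` phase window (s).
#' @param closed_end Include the sample at `t1`.
#' @return Mean activity in %SVIC.
#' @export
emg_phase_mean <- function(envelope_pct, window, closed_end = FALSE) {
  idx <- window_indices(envelope_pct, window, closed_end = closed_end)
  mean(envelope_pct$samples[idx])
}

#' All metrics of one processed trial
#'
#' Computes the full metric set from a processed trial and its segmentation:
#' rest position per scapular DOF, per-phase ROM of the scapular DOFs and
#' shoulder elevation, per-phase EMG means per muscle, scapulohumeral rhythm
#' (drink phase), trunk compensation per trunk DOF (whole task, referenced
#' to the rest posture), time-to-peak acceleration and log dimensionless
#' jerk.
#'
#' @param processed A `scap_processed` (see [process_trial()]).
#' @param seg A `scap_segmentation`.
#' @param jerk_variant Passed to [log_dimensionless_jerk()].
#' @return Tidy data frame: `metric`, `channel`, `phase`, `value`.
#' @export
trial_metrics <- function(processed, seg, jerk_variant = "speed") {
  stopifnot(inherits(seg, "scap_segmentation"))
  kin <- processed$kin
  pw <- phase_windows(seg)
  task <- c(seg$onset, seg$end)
  dofs <- c("shoulder_elev", "scap_abad", "scap_eldep", "scap_ur", "scap_wing")
  rows <- list()
  add <- function(metric, channel, phase, value) {
    rows[[length(rows) + 1L]] <<- data.frame(
      metric = metric, channel = channel, phase = phase, value = value)
  }

  for (d in c("elbow_flexext", dofs, scap_trunk_dofs)) {
    add("rest", d, NA_character_, rest_position(kin[[d]], min(5, processed$rest_duration)))
  }
  for (d in dofs) {
    for (i in seq_len(5)) {
      add("rom", d, pw$phase[i],
          range_of_motion(kin[[d]], c(pw$start[i], pw$end[i]), closed_end = (i == 5L)))
    }
  }
  for (m in names(processed$emg_pct)) {
    for (i in seq_len(5)) {
      add("emg_mean", m, pw$phase[i],
          emg_phase_mean(processed$emg_pct[[m]], c(pw$start[i], pw$end[i]),
                         closed_end = (i == 5L)))
    }
  }
  drink <- c(pw$start[3], pw$end[3])
  add("shr", NA_character_, "drink",
      scapulohumeral_rhythm(kin$shoulder_elev, kin$scap_ur, drink))
  for (d in scap_trunk_dofs) {
    neutral <- rest_position(kin[[d]], min(5, processed$rest_duration))
    add("trunk_comp", d, NA_character_, trunk_compensation(kin[[d]], task, neutral))
  }
  add("ttp_pct", NA_character_, NA_character_,
      time_to_peak_percent(processed$accel_filt, c(pw$start[1], pw$end[1]), task))
  v <- hand_velocity(processed$accel_filt, task)
  add("smoothness", NA_character_, NA_character_,
      log_dimensionless_jerk(v, variant = jerk_variant))

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Average the three central trials
#'
#' The protocol records five trials per session and analyses the mean of the
#' three central ones (trials 2--4 in execution order): the element-wise
#' arithmetic mean of their metric sets.
#'
#' @param metric_list List of per-trial metric data frames (from
#'   [trial_metrics()]) in execution order.
#' @param n_required Expected number of trials (default 5). Set `NA` to
#'   average the central trials of however many are supplied (>= 3).
#' @return A metric data frame of the same shape.
#' @export
aggregate_central_trials <- function(metric_list, n_required = 5L) {
  n <- length(metric_list)
  if (!is.na(n_required) && n != n_required) {
    stop(sprintf("expected %d trial metric sets, got %d", n_required, n), call. = FALSE)
  }
  if (n < 3L) stop("need at least 3 trials to take central trials", call. = FALSE)
  central <- metric_list[seq.int(2L, n - 1L)]
  key <- function(df) paste(df$metric, df$channel, df$phase, sep = "\r")
  k0 <- key(central[[1]])
  vals <- vapply(central, function(df) {
    if (!identical(key(df), k0)) stop("trial metric sets are not aligned", call. = FALSE)
    df$value
  }, numeric(nrow(central[[1]])))
  out <- central[[1]]
  out$value <- rowMeans(matrix(vals, nrow = nrow(out)))
  out
}
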