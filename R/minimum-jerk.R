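#' Minimum-jerk position profile
#'
#' The canonical smooth point-to-point transport primitive
#' \deqn{x(\tau) = A (10\tau^3 - 15\tau^4 + 6\tau^5), \quad \tau = t/D \in [0,1],}
#' which starts and ends at rest (zero velocity and acceleration at both
#' endpoints). Its closed-form derivatives make it the reference trajectory
#' for smoothness metrics: peak speed is \eqn{15A/(8D)} and the integral of
#' squared jerk is \eqn{720 A^2 / D^5}, so the speed-normalized dimensionless
#' jerk of a single segment is exactly \eqn{720/(15/8)^2 = 204.8}.
#'
#' @param amplitude Displacement `A` (m or deg; sign allowed).
#' @param duration Segment duration `D` in seconds (> 0).
#' @param rate Sampling rate in Hz (> 0).
#' @return A `scap_ts` of positions sampled at `t = 0, 1/rate, ..., D`
#'   (`round(D * rate) + 1` samples).
#' @seealso [log_dimensionless_jerk()]
#' @export
#' @examples
#' seg <- minimum_jerk_segment(0.25, 1.2, 100)
#' max(diff(seg$samples)) * 100 / (1.875 * 0.25 / 1.2) # ~1 at peak speed
minimum_jerk_segment <- function(amplitude, duration, rate) {
  if (!is.finite(duration) || duration <= 0) stop("`duration` must be > 0", call. = FALSE)
  if (!is.finite(rate) || rate <= 0) stop("`rate` must be > 0", call. = FALSE)
  tau <- seq(0, round(duration * rate)) / round(duration * rate)
  time_series(min_jerk_pos(tau, amplitude), rate, label = "minimum_jerk")
}

# closed-form minimum-jerk kinematics on normalized time tau in [0, 1];
# `duration` converts the tau-derivatives into per-second quantities.
min_jerk_pos <- function(tau, amplitude) {
  amplitude * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
}

min_jerk_vel <- function(tau, amplitude, duration) {
  amplitude / duration * (30 * tau^2 - 60 * tau^3 + 30 * tau^4)
}

min_jerk_acc <- function(tau, amplitude, duration) {
  amplitude / duration^2 * (60 * tau - 180 * tau^2 + 120 * tau^3)
}

min_jerk_jerk <- function(tau, amplitude, duration) {
  amplitude / duration^3 * (60 - 360 * tau + 360 * tau^2)
}
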