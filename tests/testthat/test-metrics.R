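test_that("range of motion matches analytic values and is offset-invariant", {
  expect_equal(range_of_motion(time_series(rep(7, 200), 100), c(0, 1)), 0)
  t <- seq(0, 2, by = 0.01)
  sine <- time_series(4 * sin(2 * pi * t), 100)
  expect_equal(range_of_motion(sine, c(0, 2), closed_end = TRUE), 8, tolerance = 1e-3)
  ramp <- time_series(seq(3, 17, length.out = 101), 100)
  expect_equal(range_of_motion(ramp, c(0, 1), closed_end = TRUE), 14)
  shifted <- time_series(ramp$samples + 123.4, 100)
  expect_equal(range_of_motion(shifted, c(0, 1), closed_end = TRUE), 14,
               tolerance = 1e-12)
  expect_error(range_of_motion(ramp, c(0.5, 0.5)), "window")
})

test_that("scapulohumeral rhythm is the ROM ratio with a degeneracy guard", {
  t <- seq(0, 1, by = 0.01)
  sh <- time_series(90 * t, 100)
  ur <- time_series(30 * t, 100)
  expect_equal(scapulohumeral_rhythm(sh, ur, c(0, 1)), 3)
  flat <- time_series(rep(1, 101), 100)
  expect_error(scapulohumeral_rhythm(sh, flat, c(0, 1)), "degenerate")
})

test_that("dimensionless jerk of a minimum-jerk segment hits the closed form", {
  # independent oracle: direct numerical integration of the quintic's jerk
  D <- 1.1; A <- 0.3; rate <- 2000
  tau <- seq(0, 1, length.out = round(D * rate) + 1)
  v <- scapkin:::min_jerk_vel(tau, A, D)
  j <- scapkin:::min_jerk_jerk(tau, A, D)
  dt <- D / (length(tau) - 1)
  int_j2 <- sum((j[-1]^2 + j[-length(j)]^2) / 2) * dt
  dj_oracle <- D^3 / max(v)^2 * int_j2
  expect_equal(dj_oracle, 204.8, tolerance = 1e-5)   # 720 / (15/8)^2
  ldj <- log_dimensionless_jerk(time_series(v, rate))
  expect_equal(ldj, log(204.8), tolerance = 1e-4)
  expect_equal(ldj, log(dj_oracle), tolerance = 1e-4)
})

test_that("ln(DJ) is invariant to time rescaling and amplitude scaling", {
  base <- NULL
  for (D in c(0.5, 1, 2.3)) {
    rate <- 2000
    tau <- seq(0, 1, length.out = round(D * rate) + 1)
    for (A in c(0.1, 1)) {
      v <- scapkin:::min_jerk_vel(tau, A, D)
      ldj <- log_dimensionless_jerk(time_series(v, rate))
      if (is.null(base)) base <- ldj
      expect_equal(ldj, base, tolerance = 1e-3)
    }
  }
})

test_that("superimposed velocity sub-peaks strictly raise the dimensionless jerk", {
  D <- 1; rate <- 2000
  tau <- seq(0, 1, length.out = round(D * rate) + 1)
  v0 <- scapkin:::min_jerk_vel(tau, 0.3, D)
  ldj0 <- log_dimensionless_jerk(time_series(v0, rate))
  for (k in c(2, 3, 5)) {
    v1 <- v0 + scapkin:::wiggle_vel(tau, 0.01, k, D)
    expect_gt(log_dimensionless_jerk(time_series(v1, rate)), ldj0)
  }
})

test_that("time to peak acceleration maps the analytic extremum to the task clock", {
  rate <- 2000
  D_reach <- 0.8; task <- c(0, 4)
  tau <- seq(0, 1, length.out = round(D_reach * rate) + 1)
  a <- scapkin:::min_jerk_acc(tau, 0.3, D_reach)
  full <- time_series(c(a, numeric(round((task[2] - D_reach) * rate))), rate)
  ttp <- time_to_peak_percent(full, reaching = c(0, D_reach), task = task)
  tau_pk <- (1 - 1 / sqrt(3)) / 2
  expect_equal(ttp, 100 * tau_pk * D_reach / diff(task), tolerance = 0.15)
  # constant acceleration: earliest-sample tie-break
  const <- time_series(rep(1, 4 * rate + 1), rate)
  expect_equal(time_to_peak_percent(const, c(0, D_reach), task), 0)
})

test_that("%TTP stays within [0, 100] over noisy trials", {
  cfg <- noisy_config(seed = 70)
  rc <- run_config(generator = cfg)
  for (i in 1:25) {
    tr <- generate_trial(cfg, subject_id = i, trial_index = 1, "M0")
    ps <- process_and_segment(tr, rc)
    pw <- phase_windows(ps$seg)
    ttp <- time_to_peak_percent(ps$proc$accel_filt,
                                c(pw$start[1], pw$end[1]),
                                c(ps$seg$onset, ps$seg$end))
    expect_gte(ttp, 0); expect_lte(ttp, 100)
  }
})

test_that("trunk compensation picks the signed peak deviation", {
  expect_equal(trunk_compensation(time_series(rep(2, 101), 100), c(0, 1), 2), 0)
  x <- time_series(c(rep(0, 30), rep(-5, 30), rep(2, 41)), 100)
  expect_equal(trunk_compensation(x, c(0, 1), 0), -5)
})

test_that("EMG phase mean matches analytic window means", {
  expect_equal(emg_phase_mean(time_series(rep(40, 101), 100), c(0, 1)), 40)
  step <- time_series(c(rep(20, 50), rep(60, 50)), 100)
  expect_equal(emg_phase_mean(step, c(0, 1), closed_end = TRUE), 40)
})

test_that("central-trial aggregation averages trials 2-4 and checks alignment", {
  mk <- function(v) data.frame(metric = "m", channel = NA_character_,
                               phase = NA_character_, value = v)
  lst <- lapply(1:5, mk)
  expect_equal(aggregate_central_trials(lst)$value, 3)
  same <- lapply(rep(2.5, 5), mk)
  expect_equal(aggregate_central_trials(same)$value, 2.5)
  # permuting trials 1 and 5 leaves the mean; permuting 2 and 5 changes it
  expect_equal(aggregate_central_trials(lst[c(5, 2, 3, 4, 1)])$value, 3)
  expect_equal(aggregate_central_trials(lst[c(1, 5, 3, 4, 2)])$value, 4)
  expect_error(aggregate_central_trials(lst[1:4]), "expected 5")
  expect_equal(aggregate_central_trials(lst[1:4], n_required = NA)$value, 2.5)
})

test_that("noise-free pipeline metrics equal ground truth", {
  fx <- clean_fx
  mt <- trial_metrics(fx$processed, fx$seg)
  gt <- ground_truth_df(fx$truth)
  mm <- merge(mt, gt, by = c("metric", "channel", "phase"),
              suffixes = c("_est", "_true"))
  exact <- mm[mm$metric %in% c("rest", "rom", "emg_mean", "shr", "trunk_comp"), ]
  expect_gt(nrow(exact), 60)
  expect_rel_equal(exact$value_est, exact$value_true, 1e-6)
  # whole-task quality metrics pass through the 4 Hz filter + integration
  # chain and agree approximately
  ttp <- mm[mm$metric == "ttp_pct", ]
  expect_equal(ttp$value_est, ttp$value_true, tolerance = 0.05)
  sm <- mm[mm$metric == "smoothness", ]
  expect_equal(sm$value_est, sm$value_true, tolerance = 0.02)
})
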