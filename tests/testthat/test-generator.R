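test_that("identical config and seed give bit-identical trials", {
  cfg <- noisy_config(seed = 77)
  t1 <- generate_trial(cfg, 2, 3, "M1")
  t2 <- generate_trial(cfg, 2, 3, "M1")
  expect_identical(t1$kin$shoulder_elev$samples, t2$kin$shoulder_elev$samples)
  expect_identical(t1$accel$samples, t2$accel$samples)
  expect_identical(t1$emg$MT$samples, t2$emg$MT$samples)
  # different trial index gives different noise
  t3 <- generate_trial(cfg, 2, 4, "M1")
  expect_false(identical(t1$accel$samples, t3$accel$samples))
})

test_that("noise-free construction encodes the documented event geometry", {
  fx <- clean_fx
  b <- fx$truth$boundaries
  kr <- fx$cfg$kin_rate
  el <- fx$trial$kin$elbow_flexext$samples
  sh <- fx$trial$kin$shoulder_elev$samples
  i <- function(t) round(t * kr) + 1
  # elbow extension maxima exactly at b1 and b4
  expect_equal(which.max(el[i(b[["onset"]]):i(b[["b3"]])]) + i(b[["onset"]]) - 1,
               i(b[["b1"]]))
  expect_equal(which.max(el[i(b[["b3"]]):i(b[["end"]])]) + i(b[["b3"]]) - 1,
               i(b[["b4"]]))
  # shoulder elevation flat before b2, rising after, peak at b3
  expect_equal(sd(sh[i(b[["onset"]]):i(b[["b2"]])]), 0)
  expect_gt(sh[i(b[["b2"]]) + 5] - sh[i(b[["b2"]])], 0)
  expect_equal(which.max(sh), i(b[["b3"]]))
})

test_that("shoulder/scapular coupling encodes the configured rhythm", {
  fx <- clean_fx
  b <- fx$truth$boundaries
  shr <- scapulohumeral_rhythm(fx$trial$kin$shoulder_elev,
                               fx$trial$kin$scap_ur,
                               c(b[["b2"]], b[["b3"]]))
  expect_equal(shr, 1.5, tolerance = 1e-12)
  expect_equal(fx$truth$shr, 1.5, tolerance = 1e-12)
})

test_that("rest-segment acceleration stays well inside the onset band", {
  tr <- generate_trial(noisy_config(seed = 5), 1, 1, "M0")
  rest <- tr$accel$samples[seq_len(round(5 * tr$accel$rate))]
  expect_lt(max(abs(rest - mean(rest))), 0.3)
})

test_that("SVIC generation honours amplitude, symmetry and determinism", {
  cfg0 <- clean_config()
  s <- generate_svic(cfg0, "UT")
  expect_equal(svic_reference(s), cfg0$svic_amp[["UT"]])
  s3 <- generate_svic(cfg0, "LS", rep_amps = c(0.9, 1.0, 1.1))
  expect_equal(svic_reference(s3), cfg0$svic_amp[["LS"]])
  cfgn <- noisy_config(seed = 9)
  r1 <- svic_reference(generate_svic(cfgn, "MT", subject_id = 4))
  r2 <- svic_reference(generate_svic(cfgn, "MT", subject_id = 4))
  expect_identical(r1, r2)
})

test_that("generator config validates its invariants", {
  expect_error(generator_config(phase_durations = c(1, 1, 1)), "5 values")
  expect_error(generator_config(phase_durations = c(1, 1, -1, 1, 1)), "positive")
  expect_error(generator_config(rest_duration = 3), "rest_duration")
  expect_error(generator_config(kin_rate = 2000, emg_rate = 100), "kin_rate")
  expect_error(generator_config(n_trials_per_subject = 2), "n_trials")
  expect_error(generator_config(effect_delta = list(banana = 1)), "unknown")
  expect_error(generator_config(effect_delta = list(emg = c(XX.drink = 1))),
               "MUSCLE.phase")
})

test_that("M1 applies additive effects on the generating parameters", {
  cfg <- clean_config(seed = 21,
                      effect_delta = list(emg = c(MT.forward_transport = -8),
                                          shr = 0.3))
  t0 <- generate_trial(cfg, 1, 1, "M0")
  t1 <- generate_trial(cfg, 1, 1, "M1")
  d_emg <- t1$ground_truth$emg_mean["MT", "forward_transport"] -
    t0$ground_truth$emg_mean["MT", "forward_transport"]
  expect_equal(d_emg, -8, tolerance = 0.2)  # plateau ramps blur the step slightly
  expect_equal(t1$ground_truth$shr - t0$ground_truth$shr, 0.3, tolerance = 1e-9)
  # untouched metrics identical across sessions (no noise, no trial effects)
  expect_equal(t1$ground_truth$rom["scap_wing", ], t0$ground_truth$rom["scap_wing", ])
})

test_that("smoothness perturbation adds velocity sub-peaks and raises ln(DJ)", {
  cfg0 <- clean_config(seed = 31)
  cfg1 <- clean_config(seed = 31,
                       smoothness_perturbation = list(n_subpeaks = 3, amplitude = 0.01))
  s0 <- generate_trial(cfg0, 1, 1, "M0")$ground_truth$smoothness
  s1 <- generate_trial(cfg1, 1, 1, "M0")$ground_truth$smoothness
  expect_gt(s1, s0)
})

test_that("cohort generation is complete, deterministic and ledgered", {
  cfg <- noisy_config(seed = 41, n_subjects = 2, n_trials_per_subject = 3)
  co <- generate_cohort(cfg)
  expect_length(co$subjects, 2)
  expect_length(co$subjects[[1]]$sessions$M0, 3)
  expect_length(co$subjects[[1]]$sessions$M1, 3)
  expect_setequal(names(co$subjects[[1]]$svic), scap_muscles)
  expect_true(all(c("subject", "session", "trial", "metric", "value") %in%
                    names(co$ground_truth)))
  # ledger covers every trial
  expect_equal(nrow(unique(co$ground_truth[c("subject", "session", "trial")])),
               2 * 2 * 3)
  co2 <- generate_cohort(cfg)
  expect_identical(co$ground_truth, co2$ground_truth)
})

test_that("a cohort of one is generated but refused by pre-post inference", {
  cfg <- noisy_config(seed = 51, n_subjects = 1, n_trials_per_subject = 3)
  co <- generate_cohort(cfg)
  expect_length(co$subjects, 1)
  m0 <- data.frame(x = 1); m1 <- data.frame(x = 2)
  expect_error(prepost_table(m0, m1), "3 subjects")
})
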