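test_that("onset detection matches the analytic crossing of a constructed ramp", {
  rate <- 2000
  # rest at 0 for 5 s, then a linear ramp that reaches 0.3 m/s^2 at t = 1.2 s
  # after movement begins (slope 0.25 m/s^2/s from t = 5)
  t <- seq(0, 8, by = 1 / rate)
  a <- pmax(0, t - 5) * 0.25
  onset <- detect_onset(time_series(a, rate, "m/s^2"), rest_window = 5)
  # crossing where 0.25 (t - 5) > 0.3 -> t = 6.2, within sustain/sample lag
  expect_equal(onset, 6.2, tolerance = 2 / rate + 1e-9)
  expect_gte(onset, 6.2)
})

test_that("constant acceleration yields a no-onset error", {
  x <- time_series(rep(0.05, 2000 * 7), 2000)
  expect_error(detect_onset(x, rest_window = 5), "no onset")
})

test_that("onset equals an exhaustive brute-force scan on random signals", {
  params <- segmentation_params()
  rate <- 500
  len <- max(1L, round(params$sustain_onset * rate))
  for (s in 1:100) {
    set.seed(1000 + s)
    n <- 6 * rate
    a <- rnorm(n, 0, 0.08)
    j <- sample(seq(3 * rate, 5 * rate), 1)
    a[j:n] <- a[j:n] + seq(0, 2, length.out = n - j + 1)  # guaranteed excursion
    ts <- time_series(a, rate, "m/s^2")
    got <- detect_onset(ts, rest_window = 2, params = params)
    # oracle: explicit loop over every start index
    rest_mean <- mean(a[seq_len(2 * rate)])
    dev <- abs(a - rest_mean)
    want <- NA
    for (i in seq_len(n - len + 1)) {
      if (all(dev[i:(i + len - 1)] > params$accel_threshold)) { want <- i; break }
    }
    expect_equal(got, (want - 1) / rate)
  }
})

test_that("end detection needs a return to rest and matches construction", {
  fx <- clean_fx
  endt <- detect_end(fx$processed$accel_filt, after = fx$truth$boundaries[["b4"]],
                     rest_window = 5, refine = TRUE,
                     refine_series = fx$trial$accel)
  expect_equal(endt, fx$truth$boundaries[["end"]])
  # acceleration that never re-enters the band
  rate <- 2000
  a <- c(numeric(5 * rate), rep(2, 2 * rate))
  expect_error(detect_end(time_series(a, rate), after = 5.5, rest_window = 5),
               "no end")
})

test_that("noise-free segmentation recovers every boundary exactly", {
  fx <- clean_fx
  expect_equal(unlist(unclass(fx$seg)), fx$truth$boundaries,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("segmentation boundaries are strictly increasing or error", {
  fx <- clean_fx
  b <- unlist(unclass(fx$seg))
  expect_true(all(diff(b) > 0))
  for (s in 1:20) {
    tr <- generate_trial(noisy_config(seed = 600 + s), 1, 1, "M0")
    seg <- process_and_segment(tr, clean_fx$rc)$seg
    expect_true(all(diff(unlist(unclass(seg))) > 0))
  }
})

test_that("time-shifting a clean recording shifts all boundaries equally", {
  fx <- clean_fx
  shift <- 0.5
  shifted <- fx$trial
  pad_k <- round(shift * fx$cfg$kin_rate)
  pad_e <- round(shift * fx$trial$accel$rate)
  shifted$kin <- lapply(fx$trial$kin, function(ch) {
    time_series(c(rep(ch$samples[1], pad_k), ch$samples), ch$rate, ch$units, ch$label)
  })
  shifted$accel <- time_series(c(rep(fx$trial$accel$samples[1], pad_e),
                                 fx$trial$accel$samples),
                               fx$trial$accel$rate, "m/s^2")
  shifted$rest_duration <- fx$trial$rest_duration + shift
  ps <- process_and_segment(shifted, fx$rc)
  expect_equal(unlist(unclass(ps$seg)),
               unlist(unclass(fx$seg)) + shift,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("flat shoulder elevation fails segmentation at b2 by name", {
  fx <- clean_fx
  broken <- fx$processed
  broken$kin$shoulder_elev <- time_series(
    rep(5, length(broken$kin$shoulder_elev$samples)), fx$cfg$kin_rate, "deg")
  expect_error(segment_phases(broken, fx$rc$segmentation), "b2|b3")
})

test_that("monotone elbow angle fails segmentation with a named boundary", {
  fx <- clean_fx
  broken <- fx$processed
  n <- length(broken$kin$elbow_flexext$samples)
  broken$kin$elbow_flexext <- time_series(seq(0, 1, length.out = n) * -20 + 40,
                                          fx$cfg$kin_rate, "deg")
  expect_error(segment_phases(broken, fx$rc$segmentation), "b1")
})

test_that("noisy boundary recovery stays within 50 ms for most trials", {
  # smaller companion to the acceptance sweep: 40 trials at 1 deg noise
  cfg <- noisy_config(seed = 8)
  rc <- run_config(generator = cfg)
  hit <- logical(40)
  for (i in 1:40) {
    tr <- generate_trial(cfg, subject_id = i, trial_index = 1, "M0")
    seg <- process_and_segment(tr, rc)$seg
    hit[i] <- max(abs(unlist(unclass(seg)) - tr$ground_truth$boundaries)) <= 0.05
  }
  expect_gte(mean(hit), 0.9)
})
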