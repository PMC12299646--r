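# Shared fixtures: compact task geometry (shorter phases than the study
# defaults) keeps the suite fast; everything is generated in code.

short_phases <- c(reaching = 0.8, forward_transport = 0.8, drink = 1.0,
                  backward_transport = 0.8, returning = 0.8)

clean_config <- function(seed = 11, ...) {
  generator_config(seed = seed, noise_sd_kin = 0, noise_sd_emg = 0,
                   noise_sd_accel = 0, subject_sd_frac = 0, trial_sd_frac = 0,
                   phase_durations = short_phases, rest_duration = 5.5,
                   tail_duration = 0.8, ...)
}

noisy_config <- function(seed = 12, ...) {
  generator_config(seed = seed, phase_durations = short_phases,
                   rest_duration = 5.5, tail_duration = 0.8, ...)
}

# one clean trial processed end-to-end, reused across test files
clean_fx <- local({
  cfg <- clean_config()
  rc <- run_config(generator = cfg)
  trial <- generate_trial(cfg, subject_id = 1, trial_index = 1, session = "M0")
  svic <- stats::setNames(
    lapply(scap_muscles, function(m) generate_svic(cfg, m)), scap_muscles)
  refs <- vapply(svic, svic_reference, numeric(1))
  processed <- process_trial(trial, refs, rc)
  seg <- segment_phases(processed, rc$segmentation)
  list(cfg = cfg, rc = rc, trial = trial, svic = svic, refs = refs,
       processed = processed, seg = seg,
       truth = trial$ground_truth)
})

process_and_segment <- function(trial, rc) {
  proc <- list(kin = trial$kin, accel_filt = lowpass_accel(trial$accel),
               accel_raw = trial$accel, rest_duration = trial$rest_duration)
  list(proc = proc, seg = segment_phases(proc, rc$segmentation))
}

expect_rel_equal <- function(est, truth, tol) {
  expect_lt(max(abs(est - truth) / pmax(abs(truth), 1e-12)), tol)
}
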