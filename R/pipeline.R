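# Pipeline orchestration: processing a raw trial, the run configuration
# surfacing every processing/analysis constant, and the end-to-end study
# runner (generate -> process -> segment -> metrics -> reliability ->
# pre-post).

#' Run configuration
#'
#' Bundles the generator settings, the processing constants and the analysis
#' toggles. Every processing constant of the protocol is surfaced here with
#' its published value as default: EMG band-pass 20--450 Hz order 2, RMS
#' window 100 samples, acceleration low-pass 4 Hz order 4, onset band
#' 0.3 m/s^2, 5-s rest window, alpha 0.05, power 0.80.
#'
#' @param generator A [generator_config()].
#' @param emg_band,emg_order EMG band-pass edges (Hz) and order.
#' @param rms_window RMS envelope window, samples.
#' @param accel_cutoff,accel_order Acceleration low-pass cutoff (Hz), order.
#' @param svic_central_s Central SVIC window per repetition, s.
#' @param rest_window Rest averaging window, s.
#' @param segmentation A [segmentation_params()].
#' @param jerk_variant `"speed"` or `"amplitude"` dimensionless-jerk
#'   normalization.
#' @param sem_sd SD entering the SEM: `"session1"` or `"pooled"`.
#' @param tails Tails of the design-stage power computation.
#' @param adjust Multiplicity adjustment for the pre-post table (`"none"`
#'   mirrors unadjusted reporting; `"holm"` optional).
#' @param alpha Significance / gate level.
#' @param power Design-stage target power.
#' @return A validated list of class `scap_run_config`.
#' @export
run_config <- function(generator = generator_config(),
                       emg_band = c(20, 450), emg_order = 2,
                       rms_window = 100,
                       accel_cutoff = 4, accel_order = 4,
                       svic_central_s = 3,
                       rest_window = 5,
                       segmentation = segmentation_params(),
                       jerk_variant = "speed",
                       sem_sd = "session1",
                       tails = "one",
                       adjust = "none",
                       alpha = 0.05, power = 0.80) {
  if (!jerk_variant %in% c("speed", "amplitude")) {
    stop("unknown `jerk_variant`: ", jerk_variant, call. = FALSE)
  }
  if (!sem_sd %in% c("session1", "pooled")) stop("unknown `sem_sd`", call. = FALSE)
  if (!tails %in% c("one", "two")) stop("unknown `tails`", call. = FALSE)
  if (!adjust %in% c("none", "holm")) stop("unknown `adjust`", call. = FALSE)
  stopifnot(inherits(generator, "scap_config"),
            inherits(segmentation, "scap_seg_params"))
  structure(list(generator = generator, emg_band = emg_band,
                 emg_order = emg_order, rms_window = rms_window,
                 accel_cutoff = accel_cutoff, accel_order = accel_order,
                 svic_central_s = svic_central_s, rest_window = rest_window,
                 segmentation = segmentation, jerk_variant = jerk_variant,
                 sem_sd = sem_sd, tails = tails, adjust = adjust,
                 alpha = alpha, power = power),
            class = "scap_run_config")
}

#' Process a raw trial
#'
#' Conditioning chain applied to one trial: the hand acceleration is
#' low-pass filtered (4 Hz, order 4, zero-phase); each EMG channel is
#' normalized to %SVIC and block-mean downsampled to the kinematic rate so
#' per-phase means are taken over windows defined on kinematic time. EMG
#' channels carrying attribute `raw = TRUE` are band-pass filtered and
#' RMS-enveloped first; the generator's envelope channels skip that step.
#'
#' @param trial A `scap_trial`.
#' @param svic_refs Named numeric of per-muscle SVIC reference amplitudes
#'   (from [svic_reference()]).
#' @param config A [run_config()].
#' @return A list of class `scap_processed`: `kin`, `accel_filt`,
#'   `accel_raw`, `emg_pct` (at the kinematic rate), `rest_duration`,
#'   identifiers.
#' @export
process_trial <- function(trial, svic_refs, config = run_config()) {
  stopifnot(inherits(trial, "scap_trial"))
  kr <- trial$kin[[1]]$rate
  accel_filt <- lowpass_accel(trial$accel, cutoff = config$accel_cutoff,
                              order = config$accel_order)
  emg_pct <- lapply(names(trial$emg), function(m) {
    ch <- trial$emg[[m]]
    if (isTRUE(attr(ch$samples, "raw")) || isTRUE(attr(ch, "raw"))) {
      ch <- rms_envelope(bandpass_emg(ch, band = config$emg_band,
                                      order = config$emg_order),
                         window = config$rms_window)
    }
    downsample_block_mean(normalize_to_svic(ch, svic_refs[[m]]), kr)
  })
  names(emg_pct) <- names(trial$emg)
  structure(list(kin = trial$kin, accel_filt = accel_filt,
                 accel_raw = trial$accel, emg_pct = emg_pct,
                 rest_duration = trial$rest_duration,
                 subject_id = trial$subject_id, trial_index = trial$trial_index,
                 session = trial$session),
            class = "scap_processed")
}

# stable outcome label for one metric row, e.g. "rom.scap_ur.drink"
metric_outcome_label <- function(metric, channel, phase) {
  parts <- c(metric, channel, phase)
  paste(parts[!is.na(parts)], collapse = ".")
}

#' Run the full study pipeline on a synthetic cohort
#'
#' Generates the cohort, computes SVIC references, processes and segments
#' every trial, computes per-trial metrics, averages the three central
#' trials per subject and session, and produces three results tables:
#' the tidy metrics table, the test-retest reliability table (ICC(2,k) over
#' the k repeated trials of session M0), and the pre-post comparison
#' table (M0 vs M1 trial-averages). Deterministic given the generator seed.
#'
#' @param config A [run_config()].
#' @param outcomes Optional character vector restricting the reliability and
#'   pre-post tables to specific outcome labels
#'   (`"metric.channel.phase"`); default: all metrics.
#' @return A list of class `scap_study`: `metrics` (per-trial and aggregate
#'   rows), `reliability`, `prepost`, `segmentations`, `log`.
#' @export
run_study <- function(config = run_config(), outcomes = NULL) {
  stopifnot(inherits(config, "scap_run_config"))
  gen <- config$generator
  cohort <- generate_cohort(gen)

  all_metrics <- list(); seg_rows <- list()
  for (sub in cohort$subjects) {
    refs <- vapply(sub$svic, svic_reference, numeric(1),
                   central_s = config$svic_central_s)
    for (ses in names(sub$sessions)) {
      per_trial <- list()
      for (tr in sub$sessions[[ses]]) {
        ctx <- sprintf("subject %d %s trial %d", sub$subject_id, ses, tr$trial_index)
        proc <- process_trial(tr, refs, config)
        seg <- tryCatch(segment_phases(proc, config$segmentation),
                        error = function(e) stop(ctx, ": ", conditionMessage(e),
                                                 call. = FALSE))
        mt <- trial_metrics(proc, seg, jerk_variant = config$jerk_variant)
        mt$subject <- sub$subject_id; mt$session <- ses; mt$trial <- tr$trial_index
        per_trial[[length(per_trial) + 1L]] <- mt
        seg_rows[[length(seg_rows) + 1L]] <- data.frame(
          subject = sub$subject_id, session = ses, trial = tr$trial_index,
          t(unlist(unclass(seg))))
      }
      agg <- aggregate_central_trials(lapply(per_trial, function(d) {
        d[c("metric", "channel", "phase", "value")]
      }), n_required = gen$n_trials_per_subject)
      agg$subject <- sub$subject_id; agg$session <- ses; agg$trial <- NA_integer_
      all_metrics <- c(all_metrics, per_trial, list(agg))
    }
  }
  metrics <- do.call(rbind, all_metrics)
  metrics$outcome <- mapply(metric_outcome_label, metrics$metric,
                            metrics$channel, metrics$phase, USE.NAMES = FALSE)
  rownames(metrics) <- NULL

  sel <- if (is.null(outcomes)) unique(metrics$outcome) else outcomes
  # reliability: subjects x repeated trials of session M0 (test-retest
  # across the session's k trial repetitions)
  rel_data <- metrics[metrics$session == "M0" & !is.na(metrics$trial) &
                        metrics$outcome %in% sel, ]
  rel <- reliability_table(
    data.frame(outcome = rel_data$outcome, subject = rel_data$subject,
               measurement = rel_data$trial, value = rel_data$value),
    sd_source = config$sem_sd)

  # pre-post: per-subject trial-averages, M0 vs M1
  agg_rows <- metrics[is.na(metrics$trial) & metrics$outcome %in% sel, ]
  prep <- if (gen$n_subjects < 3) {
    NULL
  } else {
    wide <- function(ses) {
      d <- agg_rows[agg_rows$session == ses, ]
      stats::reshape(d[c("subject", "outcome", "value")], idvar = "subject",
                     timevar = "outcome", direction = "wide")
    }
    w0 <- wide("M0"); w1 <- wide("M1")
    w0 <- w0[order(w0$subject), ]; w1 <- w1[order(w1$subject), ]
    colnames(w0) <- sub("^value\\.", "", colnames(w0))
    colnames(w1) <- sub("^value\\.", "", colnames(w1))
    ocs <- setdiff(colnames(w0), "subject")
    prepost_table(w0[ocs], w1[ocs], adjust = config$adjust, alpha = config$alpha)
  }
  if (is.null(prep)) {
    warning("fewer than 3 subjects: pre-post inference skipped", call. = FALSE)
  }

  structure(list(
    metrics = metrics,
    reliability = rel,
    prepost = prep,
    segmentations = do.call(rbind, seg_rows),
    ground_truth = cohort$ground_truth,
    log = list(seed = gen$seed, n_subjects = gen$n_subjects,
               n_trials = gen$n_trials_per_subject,
               emg_band = config$emg_band, rms_window = config$rms_window,
               accel_cutoff = config$accel_cutoff,
               accel_threshold = config$segmentation$accel_threshold,
               v_threshold = config$segmentation$v_threshold,
               jerk_variant = config$jerk_variant, sem_sd = config$sem_sd,
               tails = config$tails, adjust = config$adjust,
               alpha = config$alpha, power = config$power)
  ), class = "scap_study")
}

#' Write study tables to a directory
#'
#' @param study A `scap_study`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "scap_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(study$metrics, file.path(dir, "metrics.csv"), row.names = FALSE)
  utils::write.csv(study$reliability, file.path(dir, "reliability.csv"), row.names = FALSE)
  if (!is.null(study$prepost)) {
    utils::write.csv(study$prepost, file.path(dir, "prepost.csv"), row.names = FALSE)
  }
  utils::write.csv(study$segmentations, file.path(dir, "segmentations.csv"),
                   row.names = FALSE)
  utils::write.csv(study$ground_truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  writeLines(paste(names(study$log), vapply(study$log, function(x)
    paste(format(x), collapse = " "), character(1)), sep = ": "),
    file.path(dir, "run_log.txt"))
  invisible(dir)
}
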