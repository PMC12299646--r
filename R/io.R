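# Plain-text trial file format: a typed header followed by two CSV blocks,
# one per time base (kinematics at 100 Hz; acceleration + EMG at 2000 Hz).
# Times are seconds from recording start (0-based); angles are degrees with
# the sign conventions stated in the header; the commercial platform's
# binary format is out of scope (a documented extension point).

trial_kin_channels <- c("elbow_flexext", "shoulder_elev", "scap_abad",
                        "scap_eldep", "scap_ur", "scap_wing",
                        "trunk_fwflex", "trunk_axrot", "trunk_latflex")

#' Write a trial to a plain-text file
#'
#' @param trial A `scap_trial`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_trial <- function(trial, file) {
  stopifnot(inherits(trial, "scap_trial"))
  kr <- trial$kin[[1]]$rate; er <- trial$accel$rate
  con <- file(file, "w")
  on.exit(close(con))
  hdr <- c(
    "# scapkin-trial v1",
    sprintf("# subject: %d", trial$subject_id),
    sprintf("# session: %s", trial$session),
    sprintf("# trial: %d", trial$trial_index),
    sprintf("# rest_duration: %.10g", trial$rest_duration),
    "# sign-conventions: elbow extension (+); scapular abduction/elevation/upward-rotation/winging (+);",
    "#   trunk flexion (-) extension (+); trunk rotation/lateral flexion to assessed side (+)",
    sprintf("# block: kinematics rate=%g units=deg", kr))
  writeLines(hdr, con)
  kin_df <- data.frame(t = ts_times(trial$kin[[1]]),
                       lapply(trial$kin, function(x) x$samples))
  utils::write.csv(kin_df, con, row.names = FALSE, quote = FALSE)
  writeLines(sprintf("# block: highrate rate=%g units=m/s^2,au", er), con)
  hi_df <- data.frame(t = ts_times(trial$accel),
                      hand_accel = trial$accel$samples,
                      lapply(stats::setNames(trial$emg,
                                             paste0("emg_", names(trial$emg))),
                             function(x) x$samples))
  utils::write.csv(hi_df, con, row.names = FALSE, quote = FALSE)
  invisible(file)
}

parse_header_value <- function(lines, key) {
  ln <- grep(paste0("^# ", key, ":"), lines, value = TRUE)
  if (!length(ln)) stop("trial file header misses '", key, "'", call. = FALSE)
  trimws(sub(paste0("^# ", key, ":"), "", ln[1]))
}

read_block <- function(lines, start, end, declared_rate) {
  df <- utils::read.csv(text = paste(lines[start:end], collapse = "\n"))
  if (!"t" %in% names(df)) stop("block misses the time column 't'", call. = FALSE)
  dt <- diff(df$t)
  if (any(dt <= 0)) stop("non-monotone time column in trial file", call. = FALSE)
  rate_inf <- 1 / stats::median(dt)
  if (abs(rate_inf - declared_rate) / declared_rate > 0.01) {
    stop(sprintf("declared rate %g Hz does not match inferred %.3f Hz",
                 declared_rate, rate_inf), call. = FALSE)
  }
  df
}

#' Read a trial from a plain-text file
#'
#' Validates the header, channel set, time monotonicity and the agreement
#' of declared and inferred sampling rates of both blocks.
#'
#' @param file Path written by [write_trial()].
#' @return A `scap_trial` (without ground truth).
#' @export
read_trial <- function(file) {
  lines <- readLines(file)
  if (!grepl("^# scapkin-trial", lines[1])) {
    stop("not a scapkin trial file", call. = FALSE)
  }
  blocks <- grep("^# block:", lines)
  if (length(blocks) != 2L) stop("expected exactly two data blocks", call. = FALSE)
  rates <- as.numeric(sub(".*rate=([0-9.]+).*", "\\1", lines[blocks]))
  kin_df <- read_block(lines, blocks[1] + 1L, blocks[2] - 1L, rates[1])
  hi_df <- read_block(lines, blocks[2] + 1L, length(lines), rates[2])

  missing_kin <- setdiff(trial_kin_channels, names(kin_df))
  if (length(missing_kin)) {
    stop("trial file misses kinematic channel(s): ",
         paste(missing_kin, collapse = ", "), call. = FALSE)
  }
  if (!"hand_accel" %in% names(hi_df)) {
    stop("trial file misses the 'hand_accel' channel", call. = FALSE)
  }
  emg_cols <- grep("^emg_", names(hi_df), value = TRUE)
  missing_emg <- setdiff(paste0("emg_", scap_muscles), emg_cols)
  if (length(missing_emg)) {
    stop("trial file misses EMG channel(s): ",
         paste(missing_emg, collapse = ", "), call. = FALSE)
  }

  kin <- stats::setNames(lapply(trial_kin_channels, function(ch) {
    time_series(kin_df[[ch]], rates[1], "deg", ch)
  }), trial_kin_channels)
  emg <- stats::setNames(lapply(scap_muscles, function(m) {
    time_series(hi_df[[paste0("emg_", m)]], rates[2], "au", paste0("emg_", m))
  }), scap_muscles)
  trial <- list(
    kin = kin,
    accel = time_series(hi_df$hand_accel, rates[2], "m/s^2", "hand_accel"),
    emg = emg,
    rest_duration = as.numeric(parse_header_value(lines, "rest_duration")),
    subject_id = as.integer(parse_header_value(lines, "subject")),
    trial_index = as.integer(parse_header_value(lines, "trial")),
    session = parse_header_value(lines, "session"),
    ground_truth = NULL
  )
  class(trial) <- "scap_trial"
  trial
}
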