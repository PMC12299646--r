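# Synthetic recordings of the five-phase reach-drink-return task with known
# ground truth. The generator is first-class, tested code: every downstream
# stage (filtering, segmentation, metrics, reliability, pre-post inference)
# is validated against the ground truth it emits.

#' Muscles and task phases used throughout the package
#' @export
scap_muscles <- c("UT", "MT", "LT", "SAupmid", "SAlow", "LS")

#' @rdname scap_muscles
#' @export
scap_phases <- c("reaching", "forward_transport", "drink",
                 "backward_transport", "returning")

# scapular degrees of freedom carried as independent per-phase excursions
# (upward rotation is generated by coupling to shoulder elevation instead)
scap_bump_dofs <- c("scap_abad", "scap_eldep", "scap_wing")
scap_trunk_dofs <- c("trunk_fwflex", "trunk_axrot", "trunk_latflex")

default_emg_levels <- function() {
  m <- matrix(
    c(20, 25, 30, 25, 15,   # UT
      15, 20, 18, 22, 18,   # MT
      12, 18, 20, 22, 15,   # LT
      18, 22, 25, 20, 12,   # SAup/mid
      15, 20, 28, 18, 12,   # SAlow
      10, 14, 16, 14, 10),  # LS
    nrow = 6, byrow = TRUE,
    dimnames = list(scap_muscles, scap_phases)
  )
  m
}

default_rom_bumps <- function() {
  matrix(
    c(5, 3, 4, 3, 5,    # abduction/adduction
      2, 3, 2, 3, 2,    # elevation/depression
      3, 2, 2, 2, 4),   # winging
    nrow = 3, byrow = TRUE,
    dimnames = list(scap_bump_dofs, scap_phases)
  )
}

#' Configuration of the synthetic-data generator
#'
#' Collects every tunable of the synthetic drinking-task generator. Defaults
#' emulate the study conditions of the source protocol: 18 participants, five
#' trials per session, kinematics at 100 Hz, EMG/accelerometry at 2000 Hz, a
#' pre-task static rest of at least 5 s, and a five-phase
#' reach--drink--return task. Phase durations are snapped to the kinematic
#' sample grid so that true boundaries fall exactly on samples.
#'
#' @param seed Integer master seed; all randomness derives from it.
#' @param n_subjects Number of subjects in a cohort.
#' @param n_trials_per_subject Trials per session (>= 3; default 5).
#' @param kin_rate Kinematic sampling rate in Hz (default 100).
#' @param emg_rate EMG/accelerometer sampling rate in Hz (default 2000); must
#'   be an integer multiple of `kin_rate` and exceed it.
#' @param rest_duration Pre-task static rest in seconds (>= 5; default 6).
#' @param tail_duration Post-task quiet tail in seconds (default 1).
#' @param phase_durations Named or plain numeric of the five phase durations
#'   in seconds (reaching, forward transport, drink, backward transport,
#'   returning).
#' @param shr_ratio Scapulohumeral rhythm: shoulder elevation divided by
#'   scapular upward rotation (default 1.5).
#' @param shoulder_elev_amp Shoulder elevation excursion during the drink
#'   phase, degrees (default 60; the protocol analyses elevation below 120).
#' @param elbow_amp Length-2: elbow extension excursions (deg) for the
#'   reach/return segments and for the transport segments.
#' @param hand_distances Length-2: hand-path lengths (m) of the reach/return
#'   and transport minimum-jerk segments (bottle-task geometry).
#' @param rom_true 3 x 5 matrix of per-phase excursions (deg) for scapular
#'   abduction/adduction, elevation/depression and winging.
#' @param emg_level_true 6 x 5 matrix of per-phase EMG plateaus in %SVIC.
#' @param emg_rest_level Envelope level outside the task, %SVIC.
#' @param trunk_amp Named length-3: signed peak trunk deviation over the task
#'   (deg) for forward flexion, axial rotation, lateral flexion.
#' @param svic_amp Named per-muscle SVIC reference amplitudes (arbitrary
#'   acquisition units; the pipeline must recover them via normalization).
#' @param noise_sd_kin Additive white noise on angle channels, deg.
#' @param noise_sd_emg Multiplicative envelope noise, fraction of the
#'   envelope.
#' @param noise_sd_accel Additive noise on hand acceleration, m/s^2 (well
#'   inside the 0.3 m/s^2 onset band).
#' @param subject_sd_frac,trial_sd_frac Fractional between-subject and
#'   between-trial variability of excursion amplitudes and EMG levels (the
#'   subject effect is shared by both sessions, supporting ICC > 0).
#' @param effect_delta Named list of additive pre-to-post shifts applied in
#'   session M1: `emg` (named `"MUSCLE.phase"`, %SVIC), `rom` (named
#'   `"dof.phase"` or `"shoulder_elev"`, deg), `rest` (named by DOF, deg),
#'   `trunk` (named by trunk DOF, deg), `shr` (scalar), and `smoothness`
#'   (list `n_subpeaks`, `amplitude` overriding `smoothness_perturbation`).
#' @param smoothness_perturbation List `n_subpeaks` (count) and `amplitude`
#'   (m) of velocity sub-peaks superimposed on the transport segments.
#' @return A validated list of class `scap_config`.
#' @export
generator_config <- function(seed = 1L,
                             n_subjects = 18L,
                             n_trials_per_subject = 5L,
                             kin_rate = 100,
                             emg_rate = 2000,
                             rest_duration = 6,
                             tail_duration = 1,
                             phase_durations = c(reaching = 1.2,
                                                 forward_transport = 1.0,
                                                 drink = 1.5,
                                                 backward_transport = 1.0,
                                                 returning = 1.2),
                             shr_ratio = 1.5,
                             shoulder_elev_amp = 60,
                             elbow_amp = c(reach = 40, transport = 30),
                             hand_distances = c(reach = 0.30, transport = 0.25),
                             rom_true = default_rom_bumps(),
                             emg_level_true = default_emg_levels(),
                             emg_rest_level = 2,
                             trunk_amp = c(trunk_fwflex = -7,
                                           trunk_axrot = 5,
                                           trunk_latflex = -1.5),
                             svic_amp = c(UT = 1.0, MT = 0.9, LT = 1.1,
                                          SAupmid = 0.8, SAlow = 1.2, LS = 1.0),
                             noise_sd_kin = 1.0,
                             noise_sd_emg = 0.05,
                             noise_sd_accel = 0.05,
                             subject_sd_frac = 0.10,
                             trial_sd_frac = 0.05,
                             effect_delta = list(),
                             smoothness_perturbation = list(n_subpeaks = 0,
                                                            amplitude = 0)) {
  if (length(phase_durations) != 5L) {
    stop("`phase_durations` must hold exactly 5 values", call. = FALSE)
  }
  if (any(!is.finite(phase_durations)) || any(phase_durations <= 0)) {
    stop("all phase durations must be positive", call. = FALSE)
  }
  if (rest_duration < 5) stop("`rest_duration` must be >= 5 s", call. = FALSE)
  if (tail_duration <= 0) stop("`tail_duration` must be > 0", call. = FALSE)
  if (kin_rate >= emg_rate) stop("`kin_rate` must be below `emg_rate`", call. = FALSE)
  if (abs(emg_rate / kin_rate - round(emg_rate / kin_rate)) > 1e-9) {
    stop("`emg_rate` must be an integer multiple of `kin_rate`", call. = FALSE)
  }
  if (n_trials_per_subject < 3) stop("`n_trials_per_subject` must be >= 3", call. = FALSE)
  if (n_subjects < 1) stop("`n_subjects` must be >= 1", call. = FALSE)
  # snap durations to the kinematic grid so true boundaries sit on samples
  snap <- function(d) round(d * kin_rate) / kin_rate
  phase_durations <- stats::setNames(snap(phase_durations), scap_phases)
  if (any(phase_durations <= 0)) stop("phase durations collapse on the sample grid", call. = FALSE)
  rest_duration <- snap(rest_duration)
  tail_duration <- snap(tail_duration)
  stopifnot(identical(dim(rom_true), c(3L, 5L)),
            identical(dim(emg_level_true), c(6L, 5L)))
  dimnames(rom_true) <- list(scap_bump_dofs, scap_phases)
  dimnames(emg_level_true) <- list(scap_muscles, scap_phases)
  cfg <- list(
    seed = as.integer(seed), n_subjects = as.integer(n_subjects),
    n_trials_per_subject = as.integer(n_trials_per_subject),
    kin_rate = kin_rate, emg_rate = emg_rate,
    rest_duration = rest_duration, tail_duration = tail_duration,
    phase_durations = phase_durations, shr_ratio = shr_ratio,
    shoulder_elev_amp = shoulder_elev_amp, elbow_amp = elbow_amp,
    hand_distances = hand_distances, rom_true = rom_true,
    emg_level_true = emg_level_true, emg_rest_level = emg_rest_level,
    trunk_amp = trunk_amp, svic_amp = svic_amp,
    noise_sd_kin = noise_sd_kin, noise_sd_emg = noise_sd_emg,
    noise_sd_accel = noise_sd_accel,
    subject_sd_frac = subject_sd_frac, trial_sd_frac = trial_sd_frac,
    effect_delta = validate_effect_delta(effect_delta),
    smoothness_perturbation = smoothness_perturbation,
    # fixed rest-posture baselines (deg); also the rest-position ground truth
    baselines = c(elbow_flexext = 10, shoulder_elev = 5, scap_abad = 30,
                  scap_eldep = 5, scap_ur = 2, scap_wing = 3,
                  trunk_fwflex = 0, trunk_axrot = 0, trunk_latflex = 0)
  )
  class(cfg) <- "scap_config"
  cfg
}

validate_effect_delta <- function(fx) {
  if (length(fx) == 0L) return(list())
  allowed <- c("emg", "rom", "rest", "trunk", "shr", "smoothness")
  bad <- setdiff(names(fx), allowed)
  if (length(bad)) stop("unknown effect_delta component(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  if (!is.null(fx$emg)) {
    parts <- strsplit(names(fx$emg), ".", fixed = TRUE)
    ok <- vapply(parts, function(p) length(p) == 2 && p[1] %in% scap_muscles &&
                   p[2] %in% scap_phases, logical(1))
    if (!all(ok)) stop("effect_delta$emg names must be 'MUSCLE.phase'", call. = FALSE)
  }
  if (!is.null(fx$rom)) {
    parts <- strsplit(names(fx$rom), ".", fixed = TRUE)
    ok <- vapply(parts, function(p) {
      (length(p) == 2 && p[1] %in% scap_bump_dofs && p[2] %in% scap_phases) ||
        identical(p, "shoulder_elev")
    }, logical(1))
    if (!all(ok)) stop("effect_delta$rom names must be 'dof.phase' or 'shoulder_elev'",
                       call. = FALSE)
  }
  if (!is.null(fx$trunk) && !all(names(fx$trunk) %in% scap_trunk_dofs)) {
    stop("effect_delta$trunk names must be trunk DOFs", call. = FALSE)
  }
  fx
}

# deterministic sub-seed derivation; keeps everything below 2^31 - 1
derive_seed <- function(seed, subject = 0L, trial = 0L, m1 = 0L, salt = 0L) {
  as.integer((as.double(seed) + 7919 * subject + 104729 * trial +
                1299709 * m1 + 15485863 * salt) %% 2147483647)
}

# task boundary times (s): onset, b1..b4, end
task_boundaries <- function(config) {
  tb <- config$rest_duration + cumsum(c(0, unname(config$phase_durations)))
  stats::setNames(tb, c("onset", "b1", "b2", "b3", "b4", "end"))
}

# per-subject/per-trial multiplicative amplitude factors (shared across the
# channels of one family); subject factor identical in M0 and M1
trial_factors <- function(config, subject_id, trial_index) {
  set.seed(derive_seed(config$seed, subject_id, 0L, 0L, salt = 1L))
  subj <- list(
    rom = pmax(0.5, 1 + stats::rnorm(3, 0, config$subject_sd_frac)),
    shoulder = pmax(0.5, 1 + stats::rnorm(1, 0, config$subject_sd_frac)),
    emg = pmax(0.5, 1 + stats::rnorm(6, 0, config$subject_sd_frac)),
    trunk = pmax(0.5, 1 + stats::rnorm(3, 0, config$subject_sd_frac))
  )
  set.seed(derive_seed(config$seed, subject_id, trial_index, 0L, salt = 2L))
  tri <- list(
    rom = pmax(0.5, 1 + stats::rnorm(3, 0, config$trial_sd_frac)),
    shoulder = pmax(0.5, 1 + stats::rnorm(1, 0, config$trial_sd_frac)),
    emg = pmax(0.5, 1 + stats::rnorm(6, 0, config$trial_sd_frac)),
    trunk = pmax(0.5, 1 + stats::rnorm(3, 0, config$trial_sd_frac))
  )
  list(rom = subj$rom * tri$rom,
       shoulder = subj$shoulder * tri$shoulder,
       emg = subj$emg * tri$emg,
       trunk = subj$trunk * tri$trunk)
}

# resolve session-dependent generator parameters (M1 applies effect_delta)
session_params <- function(config, session, factors) {
  p <- list(
    shr = config$shr_ratio,
    shoulder_amp = config$shoulder_elev_amp * factors$shoulder,
    rom = config$rom_true * factors$rom,
    emg = config$emg_level_true * factors$emg,
    trunk = config$trunk_amp * factors$trunk,
    baselines = config$baselines,
    smooth = config$smoothness_perturbation
  )
  if (identical(session, "M1") && length(config$effect_delta)) {
    fx <- config$effect_delta
    if (!is.null(fx$emg)) for (nm in names(fx$emg)) {
      mp <- strsplit(nm, ".", fixed = TRUE)[[1]]
      p$emg[mp[1], mp[2]] <- max(0, p$emg[mp[1], mp[2]] + fx$emg[[nm]])
    }
    if (!is.null(fx$rom)) for (nm in names(fx$rom)) {
      if (nm == "shoulder_elev") {
        p$shoulder_amp <- max(1, p$shoulder_amp + fx$rom[[nm]])
      } else {
        mp <- strsplit(nm, ".", fixed = TRUE)[[1]]
        p$rom[mp[1], mp[2]] <- max(0, p$rom[mp[1], mp[2]] + fx$rom[[nm]])
      }
    }
    if (!is.null(fx$rest)) for (nm in names(fx$rest)) {
      p$baselines[nm] <- p$baselines[nm] + fx$rest[[nm]]
    }
    if (!is.null(fx$trunk)) for (nm in names(fx$trunk)) {
      p$trunk[nm] <- p$trunk[nm] + fx$trunk[[nm]]
    }
    if (!is.null(fx$shr)) p$shr <- p$shr + fx$shr
    if (!is.null(fx$smoothness)) p$smooth <- fx$smoothness
  }
  p
}

# smooth transition kernel for EMG plateaus: centred Hann window
smooth_steps <- function(x, rate, ramp_s = 0.1) {
  k <- round(ramp_s * rate)
  if (k < 2) return(x)
  if (k %% 2 == 0) k <- k + 1
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(k) / (k + 1))
  w <- w / sum(w)
  xp <- c(rep(x[1], k), x, rep(x[length(x)], k))
  y <- stats::filter(xp, w, sides = 2)
  as.numeric(y[(k + 1):(k + length(x))])
}

# velocity/acceleration of the superimposed sub-peak wiggle on normalized
# time tau in [0,1]; w(tau) = a sin^2(pi tau) sin(2 pi k tau) (C2 at joins)
wiggle_vel <- function(tau, a, k, duration) {
  s <- sin(pi * tau)
  a * pi * (sin(2 * pi * tau) * sin(2 * pi * k * tau) +
              2 * k * s^2 * cos(2 * pi * k * tau)) / duration
}

wiggle_acc <- function(tau, a, k, duration) {
  s <- sin(pi * tau)
  2 * a * pi^2 * (cos(2 * pi * tau) * sin(2 * pi * k * tau) +
                    2 * k * sin(2 * pi * tau) * cos(2 * pi * k * tau) -
                    2 * k^2 * s^2 * sin(2 * pi * k * tau)) / duration^2
}

#' Generate one synthetic drinking-task trial with ground truth
#'
#' Builds a complete `TrialRecording`: eleven kinematic channels at the
#' kinematic rate, signed hand-path acceleration and six EMG amplitude
#' envelopes at the high rate, preceded by a static rest segment whose
#' acceleration fluctuation stays well inside the 0.3 m/s^2 onset band.
#' Hand-path transport segments are minimum-jerk; the elbow shows extension
#' maxima exactly at the reaching/forward-transport and
#' backward-transport/returning boundaries; shoulder elevation starts rising
#' at the drink-phase onset and peaks at the drink/backward-transport
#' boundary; scapular upward rotation tracks shoulder elevation divided by
#' `shr_ratio`. Session `"M1"` applies the configured `effect_delta` shifts.
#'
#' @param config A [generator_config()].
#' @param subject_id Subject index (drives the subject-level random effect,
#'   shared by both sessions).
#' @param trial_index Trial number within the session.
#' @param session `"M0"` (baseline) or `"M1"` (post).
#' @return A list of class `scap_trial` with elements `kin` (named list of
#'   `scap_ts` at `kin_rate`), `accel` (signed path acceleration, 2000 Hz),
#'   `emg` (named list of amplitude envelopes, acquisition units),
#'   `rest_duration`, identifiers, and `ground_truth` (class `scap_truth`).
#' @export
generate_trial <- function(config, subject_id = 1L, trial_index = 1L,
                           session = c("M0", "M1")) {
  stopifnot(inherits(config, "scap_config"))
  session <- match.arg(session)
  factors <- trial_factors(config, subject_id, trial_index)
  p <- session_params(config, session, factors)

  kr <- config$kin_rate; er <- config$emg_rate
  tb <- task_boundaries(config)
  total <- tb[["end"]] + config$tail_duration
  n_kin <- round(total * kr) + 1L
  n_emg <- round(total * er) + 1L
  ib_k <- round(tb * kr) + 1L   # boundary sample indices, kinematic grid
  ib_e <- round(tb * er) + 1L   # boundary sample indices, high-rate grid
  durs <- unname(config$phase_durations)

  # --- noise-free kinematic channels ----------------------------------------
  phase_tau <- function(n_grid, ib, ph) {
    idx <- ib[ph + 1L]:ib[ph + 2L]   # phase ph spans boundaries ph..ph+1
    list(idx = idx, tau = (idx - idx[1]) / (idx[length(idx)] - idx[1]))
  }
  bl <- p$baselines

  elbow <- rep(bl[["elbow_flexext"]], n_kin)
  a_reach <- config$elbow_amp[["reach"]] * factors$shoulder  # tied to arm excursion scale
  a_trans <- config$elbow_amp[["transport"]] * factors$shoulder
  half_cos_up <- function(tau, a) a * (1 - cos(pi * tau)) / 2
  pt <- phase_tau(n_kin, ib_k, 0L)  # reaching
  elbow[pt$idx] <- bl[["elbow_flexext"]] + half_cos_up(pt$tau, a_reach)
  pt <- phase_tau(n_kin, ib_k, 1L)  # forward transport
  elbow[pt$idx] <- bl[["elbow_flexext"]] + a_reach - half_cos_up(pt$tau, a_trans)
  drink_lvl <- bl[["elbow_flexext"]] + a_reach - a_trans
  pt <- phase_tau(n_kin, ib_k, 2L)  # drink: elbow held
  elbow[pt$idx] <- drink_lvl
  pt <- phase_tau(n_kin, ib_k, 3L)  # backward transport
  elbow[pt$idx] <- drink_lvl + half_cos_up(pt$tau, a_trans)
  pt <- phase_tau(n_kin, ib_k, 4L)  # returning
  elbow[pt$idx] <- bl[["elbow_flexext"]] + a_reach - half_cos_up(pt$tau, a_reach)
  elbow[ib_k[["end"]]:n_kin] <- bl[["elbow_flexext"]]

  shoulder <- rep(bl[["shoulder_elev"]], n_kin)
  pt <- phase_tau(n_kin, ib_k, 2L)  # drink: quarter-sine rise, peak at b3
  shoulder[pt$idx] <- bl[["shoulder_elev"]] + p$shoulder_amp * sin(pi * pt$tau / 2)
  pt <- phase_tau(n_kin, ib_k, 3L)  # backward transport: quarter-cosine descent
  shoulder[pt$idx] <- bl[["shoulder_elev"]] + p$shoulder_amp * cos(pi * pt$tau / 2)

  scap_ur <- bl[["scap_ur"]] + (shoulder - bl[["shoulder_elev"]]) / p$shr

  bump_channel <- function(base, amps) {
    x <- rep(base, n_kin)
    for (ph in 0:4) {
      pt <- phase_tau(n_kin, ib_k, ph)
      x[pt$idx] <- base + amps[ph + 1L] * sin(pi * pt$tau)
    }
    x
  }
  abad <- bump_channel(bl[["scap_abad"]], p$rom["scap_abad", ])
  eldep <- bump_channel(bl[["scap_eldep"]], p$rom["scap_eldep", ])
  wing <- bump_channel(bl[["scap_wing"]], p$rom["scap_wing", ])

  trunk_channel <- function(base, amp) {
    x <- rep(base, n_kin)
    idx <- ib_k[["onset"]]:ib_k[["end"]]
    tau <- (idx - idx[1]) / (idx[length(idx)] - idx[1])
    x[idx] <- base + amp * sin(pi * tau)
    x
  }
  trunk <- lapply(scap_trunk_dofs, function(d) trunk_channel(bl[[d]], p$trunk[[d]]))
  names(trunk) <- scap_trunk_dofs

  kin_clean <- c(
    list(elbow_flexext = elbow, shoulder_elev = shoulder, scap_abad = abad,
         scap_eldep = eldep, scap_ur = scap_ur, scap_wing = wing),
    trunk
  )

  # --- noise-free hand acceleration / velocity (high-rate grid) -------------
  accel <- numeric(n_emg)
  vel <- numeric(n_emg)
  amps_m <- c(config$hand_distances[["reach"]], config$hand_distances[["transport"]],
              0, -config$hand_distances[["transport"]], -config$hand_distances[["reach"]])
  n_sub <- p$smooth$n_subpeaks %||% 0
  a_sub <- p$smooth$amplitude %||% 0
  for (ph in 0:4) {
    pt <- phase_tau(n_emg, ib_e, ph)
    A <- amps_m[ph + 1L]; D <- durs[ph + 1L]
    if (A != 0) {
      accel[pt$idx] <- min_jerk_acc(pt$tau, A, D)
      vel[pt$idx] <- min_jerk_vel(pt$tau, A, D)
    }
    if (n_sub > 0 && a_sub > 0 && ph %in% c(1L, 3L)) {  # transport phases
      accel[pt$idx] <- accel[pt$idx] + wiggle_acc(pt$tau, a_sub, n_sub, D)
      vel[pt$idx] <- vel[pt$idx] + wiggle_vel(pt$tau, a_sub, n_sub, D)
    }
  }

  # --- noise-free EMG envelopes (acquisition units) -------------------------
  t_emg <- (seq_len(n_emg) - 1) / er
  phase_of <- findInterval(t_emg, tb, left.open = FALSE)  # 0 rest, 1..5 phases, 6 tail
  env_clean <- lapply(scap_muscles, function(m) {
    lvl <- c(config$emg_rest_level, p$emg[m, ], config$emg_rest_level)[phase_of + 1L]
    env_pct <- smooth_steps(lvl, er, ramp_s = 0.1)
    env_pct * config$svic_amp[[m]] / 100
  })
  names(env_clean) <- scap_muscles

  # --- ground truth from the noise-free construction ------------------------
  truth <- compute_ground_truth(config, p, tb, kin_clean, accel, vel, env_clean)

  # --- noise injection ------------------------------------------------------
  set.seed(derive_seed(config$seed, subject_id, trial_index,
                       as.integer(session == "M1"), salt = 3L))
  kin <- lapply(kin_clean, function(x) x + stats::rnorm(n_kin, 0, config$noise_sd_kin))
  accel_n <- accel + stats::rnorm(n_emg, 0, config$noise_sd_accel)
  emg <- lapply(env_clean, function(e) {
    pmax(0, e * (1 + stats::rnorm(n_emg, 0, config$noise_sd_emg)))
  })

  kin_units <- "deg"
  trial <- list(
    kin = stats::setNames(lapply(names(kin), function(nm) {
      time_series(kin[[nm]], kr, kin_units, nm)
    }), names(kin)),
    accel = time_series(accel_n, er, "m/s^2", "hand_accel"),
    emg = stats::setNames(lapply(scap_muscles, function(m) {
      time_series(emg[[m]], er, "au", paste0("emg_", m))
    }), scap_muscles),
    rest_duration = config$rest_duration,
    subject_id = subject_id, trial_index = trial_index, session = session,
    ground_truth = truth
  )
  class(trial) <- "scap_trial"
  trial
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# definitional metric values computed from the noise-free arrays and the
# known boundaries (independent of the detection path)
compute_ground_truth <- function(config, p, tb, kin_clean, accel, vel, env_clean) {
  kr <- config$kin_rate; er <- config$emg_rate
  win <- function(ph) c(tb[[ph + 1L]], tb[[ph + 2L]])
  dofs <- c("shoulder_elev", "scap_abad", "scap_eldep", "scap_ur", "scap_wing")

  as_ts <- function(x, rate) time_series(x, rate)
  rom <- matrix(NA_real_, length(dofs), 5, dimnames = list(dofs, scap_phases))
  for (d in dofs) {
    ts <- as_ts(kin_clean[[d]], kr)
    for (ph in 0:4) {
      idx <- window_indices(ts, win(ph), closed_end = (ph == 4L))
      rom[d, ph + 1L] <- max(ts$samples[idx]) - min(ts$samples[idx])
    }
  }

  emg_mean <- matrix(NA_real_, 6, 5, dimnames = list(scap_muscles, scap_phases))
  for (m in scap_muscles) {
    env_pct <- env_clean[[m]] * 100 / config$svic_amp[[m]]
    env_kin <- downsample_block_mean(as_ts(env_pct, er), kr)
    for (ph in 0:4) {
      idx <- window_indices(env_kin, win(ph), closed_end = (ph == 4L))
      emg_mean[m, ph + 1L] <- mean(env_kin$samples[idx])
    }
  }

  trunk_comp <- vapply(scap_trunk_dofs, function(d) {
    ts <- as_ts(kin_clean[[d]], kr)
    idx <- window_indices(ts, c(tb[["onset"]], tb[["end"]]), closed_end = TRUE)
    dev <- ts$samples[idx] - p$baselines[[d]]
    dev[which.max(abs(dev))]
  }, numeric(1))

  acc_ts <- as_ts(accel, er)
  idx_r <- window_indices(acc_ts, win(0L))
  t_pk <- (idx_r[argmax_earliest(abs(accel[idx_r]))] - 1) / er
  ttp <- 100 * (t_pk - tb[["onset"]]) / (tb[["end"]] - tb[["onset"]])

  vel_ts <- as_ts(vel, er)
  idx_task <- window_indices(vel_ts, c(tb[["onset"]], tb[["end"]]), closed_end = TRUE)
  smooth <- log_dimensionless_jerk_samples(vel[idx_task], er)

  truth <- list(
    boundaries = tb,
    rest = p$baselines[c("elbow_flexext", dofs, scap_trunk_dofs)],
    rom = rom,
    emg_mean = emg_mean,
    shr = rom["shoulder_elev", "drink"] / rom["scap_ur", "drink"],
    trunk_comp = trunk_comp,
    ttp_pct = ttp,
    smoothness = smooth
  )
  class(truth) <- "scap_truth"
  truth
}

#' Generate an SVIC recording for one muscle
#'
#' Three 5-s constant-plus-noise amplitude envelopes at the muscle's known
#' reference amplitude, emulating the submaximal isometric normalization
#' recordings.
#'
#' @param config A [generator_config()].
#' @param muscle One of `scap_muscles`.
#' @param subject_id Subject index (seeds the noise).
#' @param rep_amps Optional length-3 multipliers of the reference amplitude
#'   per repetition (default all 1).
#' @return A list of class `scap_svic`: `muscle`, `repetitions` (three
#'   `scap_ts` of 5 s at `emg_rate`).
#' @export
generate_svic <- function(config, muscle, subject_id = 1L, rep_amps = c(1, 1, 1)) {
  stopifnot(inherits(config, "scap_config"))
  muscle <- match.arg(muscle, scap_muscles)
  if (length(rep_amps) != 3L) stop("`rep_amps` must have length 3", call. = FALSE)
  set.seed(derive_seed(config$seed, subject_id, 0L, 0L,
                       salt = 10L + match(muscle, scap_muscles)))
  n <- round(5 * config$emg_rate) + 1L
  amp <- config$svic_amp[[muscle]]
  reps <- lapply(rep_amps, function(a) {
    x <- pmax(0, amp * a * (1 + stats::rnorm(n, 0, config$noise_sd_emg)))
    time_series(x, config$emg_rate, "au", paste0("svic_", muscle))
  })
  structure(list(muscle = muscle, repetitions = reps), class = "scap_svic")
}

#' Generate a paired pre/post cohort with a ground-truth ledger
#'
#' For every subject: one SVIC set and `n_trials_per_subject` trials in each
#' of the two sessions (M0 baseline, M1 post). Session M1 applies the
#' configured `effect_delta`. The ledger records every ground-truth metric of
#' every trial in tidy long format.
#'
#' @param config A [generator_config()] with `n_subjects >= 2` (a cohort of
#'   one is generated with a warning; downstream inference will refuse it).
#' @return A list of class `scap_cohort`: `subjects` (per subject: `svic`
#'   refs-recordings and `sessions$M0` / `sessions$M1` trial lists),
#'   `ground_truth` (long data frame), `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "scap_config"))
  subjects <- lapply(seq_len(config$n_subjects), function(s) {
    svic <- lapply(scap_muscles, function(m) generate_svic(config, m, subject_id = s))
    names(svic) <- scap_muscles
    sessions <- lapply(c(M0 = "M0", M1 = "M1"), function(ses) {
      lapply(seq_len(config$n_trials_per_subject), function(tr) {
        generate_trial(config, subject_id = s, trial_index = tr, session = ses)
      })
    })
    list(subject_id = s, svic = svic, sessions = sessions)
  })
  ledger <- do.call(rbind, lapply(subjects, function(sub) {
    do.call(rbind, lapply(names(sub$sessions), function(ses) {
      do.call(rbind, lapply(sub$sessions[[ses]], function(tr) {
        df <- ground_truth_df(tr$ground_truth)
        df$subject <- sub$subject_id; df$session <- ses; df$trial <- tr$trial_index
        df
      }))
    }))
  }))
  ledger <- ledger[, c("subject", "session", "trial", "metric", "channel", "phase", "value")]
  structure(list(subjects = subjects, ground_truth = ledger, config = config),
            class = "scap_cohort")
}

#' Ground truth as a tidy data frame
#'
#' @param truth A `scap_truth` as attached to generated trials.
#' @return Data frame with columns `metric`, `channel`, `phase`, `value`.
#' @export
ground_truth_df <- function(truth) {
  stopifnot(inherits(truth, "scap_truth"))
  rows <- list(
    data.frame(metric = "boundary", channel = NA_character_,
               phase = names(truth$boundaries), value = unname(truth$boundaries)),
    data.frame(metric = "rest", channel = names(truth$rest),
               phase = NA_character_, value = unname(truth$rest)),
    do.call(rbind, lapply(rownames(truth$rom), function(d) {
      data.frame(metric = "rom", channel = d, phase = colnames(truth$rom),
                 value = unname(truth$rom[d, ]))
    })),
    do.call(rbind, lapply(rownames(truth$emg_mean), function(m) {
      data.frame(metric = "emg_mean", channel = m, phase = colnames(truth$emg_mean),
                 value = unname(truth$emg_mean[m, ]))
    })),
    data.frame(metric = "shr", channel = NA_character_, phase = "drink",
               value = truth$shr),
    data.frame(metric = "trunk_comp", channel = names(truth$trunk_comp),
               phase = NA_character_, value = unname(truth$trunk_comp)),
    data.frame(metric = "ttp_pct", channel = NA_character_,
               phase = NA_character_, value = truth$ttp_pct),
    data.frame(metric = "smoothness", channel = NA_character_,
               phase = NA_character_, value = truth$smoothness)
  )
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
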