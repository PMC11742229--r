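# minimum-jerk shape functions on normalised time u in [0, 1]
mj_pos_shape <- function(u) {
  u <- pmin(1, pmax(0, u))
  10 * u^3 - 15 * u^4 + 6 * u^5
}
mj_vel_shape <- function(u) {
  out <- numeric(length(u))
  in01 <- u > 0 & u < 1
  v <- u[in01]
  out[in01] <- 30 * v^2 * (1 - v)^2
  out
}

#' Minimum-jerk point-to-point segment
#'
#' The quintic minimum-jerk trajectory is the standard model of smooth
#' unimpaired reaching: position `A (10u^3 - 15u^4 + 6u^5)` with
#' `u = t / T`, giving a single-peaked bell speed profile with maximum
#' `1.875 A / T` at mid-movement.
#'
#' @param duration segment duration T in s (> 0).
#' @param amplitude movement amplitude A in mm (> 0).
#' @param sampling_rate sampling frequency in Hz.
#' @return tibble with `time` (s), `position` (mm) and `speed` (mm/s).
#' @export
#' @examples
#' seg <- minimum_jerk_segment(1, 300, 240)
#' max(seg$speed) # ~562.5 = 1.875 * 300 / 1
minimum_jerk_segment <- function(duration, amplitude, sampling_rate = 240) {
  if (duration <= 0 || amplitude <= 0 || sampling_rate <= 0) {
    abort("duration, amplitude and sampling_rate must be positive",
          class = "scedrink_invalid_input")
  }
  t <- seq(0, duration, by = 1 / sampling_rate)
  u <- t / duration
  tibble::tibble(time = t,
                 position = amplitude * mj_pos_shape(u),
                 speed = amplitude / duration * mj_vel_shape(u))
}

#' Specification of a synthetic drinking trial
#'
#' Describes one simulated drinking-task trial: five phase durations
#' (reach, forward transport, drinking pause, back transport, return),
#' the task geometry, optional injected submovements, a programmed
#' forward trunk excursion, and isotropic Gaussian marker noise. Defaults
#' reflect the standardized task (cup 300 mm from the table edge, 240 Hz
#' capture) at a comfortable self-paced speed.
#'
#' @param phase_durations named/ordered numeric of 5 positive durations in
#'   s: reach, forward, drink, back, return.
#' @param reach_distance distance from hand start to the cup in mm.
#' @param lift_height cup elevation at the mouth in mm.
#' @param submovements data frame with columns `phase` (1 reach, 2 forward
#'   transport, 3 back transport, 4 return), `at` (onset within the phase,
#'   s), `amplitude` (peak speed of the injected bump, mm/s), `width`
#'   (bump duration, s). Injections below the 20 mm/s amplitude limit or
#'   closer than 150 ms to another peak are generated but marked
#'   non-qualifying in the ground truth.
#' @param trunk_excursion programmed forward trunk compensation in mm.
#' @param noise_sd isotropic Gaussian noise per coordinate per frame in mm
#'   (default 0.2, typical optical-capture jitter).
#' @param sampling_rate Hz (study value 240).
#' @param pad stationary padding before and after the movement in s.
#' @param seed integer seed for the noise.
#' @param participant_id,trial_id identifiers stamped on the trajectory.
#' @return object of class `synthetic_trial_spec` (a validated list).
#' @export
synthetic_trial_spec <- function(phase_durations = c(reach = 1.5, forward = 1.2,
                                                     drink = 2, back = 1.2,
                                                     return_ = 1.5),
                                 reach_distance = 300, lift_height = 200,
                                 submovements = NULL, trunk_excursion = 30,
                                 noise_sd = 0.2, sampling_rate = 240,
                                 pad = 0.5, seed = 1L,
                                 participant_id = "SYN", trial_id = "t1") {
  if (length(phase_durations) != 5 || any(phase_durations <= 0)) {
    abort("phase_durations must be 5 positive durations",
          class = "scedrink_invalid_input")
  }
  if (reach_distance <= 0 || lift_height <= 0 || noise_sd < 0 ||
      sampling_rate <= 0 || pad < 0) {
    abort("invalid geometry/noise/sampling parameters",
          class = "scedrink_invalid_input")
  }
  if (is.null(submovements)) {
    submovements <- data.frame(phase = integer(0), at = numeric(0),
                               amplitude = numeric(0), width = numeric(0))
  }
  submovements <- as.data.frame(submovements)
  transport_durs <- phase_durations[c(1, 2, 4, 5)]
  if (nrow(submovements) > 0) {
    stopifnot(all(c("phase", "at", "amplitude", "width") %in%
                    names(submovements)))
    if (any(!submovements$phase %in% 1:4) || any(submovements$amplitude < 0) ||
        any(submovements$width <= 0) ||
        any(submovements$at < 0 |
            submovements$at + submovements$width >
              transport_durs[submovements$phase])) {
      abort("each submovement must fit inside its transport phase",
            class = "scedrink_invalid_input")
    }
  }
  structure(list(phase_durations = unname(phase_durations),
                 reach_distance = reach_distance, lift_height = lift_height,
                 submovements = submovements,
                 trunk_excursion = trunk_excursion, noise_sd = noise_sd,
                 sampling_rate = sampling_rate, pad = pad,
                 seed = as.integer(seed),
                 participant_id = participant_id, trial_id = trial_id),
            class = "synthetic_trial_spec")
}

# scalar speed and scalar displacement along a phase's path, including
# injected submovement bumps; t_local is time within the phase
phase_profile <- function(t_local, duration, amplitude, subs) {
  disp_each <- if (nrow(subs)) subs$amplitude * subs$width / 1.875 else numeric(0)
  a_eff <- amplitude - sum(disp_each)
  u <- t_local / duration
  pos <- a_eff * mj_pos_shape(u)
  vel <- a_eff / duration * mj_vel_shape(u)
  if (nrow(subs)) {
    for (k in seq_len(nrow(subs))) {
      us <- (t_local - subs$at[k]) / subs$width[k]
      pos <- pos + disp_each[k] * mj_pos_shape(us)
      vel <- vel + subs$amplitude[k] * mj_vel_shape(us) / 1.875
    }
  }
  list(pos = pos, vel = vel)
}

threshold_crossing_times <- function(speed, fs, fraction = 0.02) {
  thr <- fraction * max(speed)
  above <- speed > thr
  idx <- which(above)
  c(first = (idx[1] - 1) / fs, last = (idx[length(idx)] + 1 - 1) / fs,
    threshold = thr)
}

#' Generate a synthetic drinking trial with ground truth
#'
#' Composes hand, cup and trunk marker paths from minimum-jerk segments:
#' the hand reaches the cup, transports it up to the mouth, pauses for the
#' drink, returns it to the table and goes back to the start; the trunk
#' performs the programmed forward excursion during the transport. Injected
#' submovements are superposed as minimum-jerk speed bumps along the path
#' (the main segment amplitude is rescaled so the end points are
#' preserved). Seeded isotropic Gaussian noise is added to every
#' coordinate.
#'
#' The returned ground truth is computed from the noiseless analytic
#' profiles, independent of the extraction pipeline: the 2%-of-peak
#' crossing onset/offset and movement time of the hand speed, the
#' cup-motion bout boundaries, the qualifying-submovement unit count
#' (4 plus every injection with amplitude > 20 mm/s whose peak is at
#' least 150 ms from the phase's main peak and from other qualifying
#' peaks), and the programmed trunk excursion.
#'
#' @param spec a [synthetic_trial_spec()].
#' @return list with `trajectory` (a [marker_trajectory()]) and
#'   `ground_truth` (onset, offset, movement_time, boundaries,
#'   n_movement_units, units_per_phase, qualifying flags per injection,
#'   trunk_displacement in cm, peak_hand_speed, noiseless hand/cup speed
#'   series).
#' @export
generate_trial <- function(spec) {
  stopifnot(inherits(spec, "synthetic_trial_spec"))
  fs <- spec$sampling_rate
  d <- spec$phase_durations
  pad_n <- round(spec$pad * fs)
  total <- sum(d)
  n_move <- round(total * fs)
  n <- pad_n + n_move + 1 + pad_n
  t <- (seq_len(n) - 1) / fs
  t0 <- spec$pad            # movement start time
  starts <- t0 + cumsum(c(0, d))[1:5]
  ends <- starts + d

  # geometry (mm): X forward, Y lateral, Z up
  hand0 <- c(0, 0, 0)
  cup0 <- c(spec$reach_distance, 0, 0)
  mouth <- c(30, 0, spec$lift_height)
  waypoints <- list(hand0, cup0, mouth, mouth, cup0, hand0)
  # transport phase index (1..4) for overall segments 1,2,4,5
  seg_to_transport <- c(1, 2, NA, 3, 4)

  hand <- matrix(rep(hand0, each = n), n, 3)
  hand_speed_true <- numeric(n)
  for (seg in 1:5) {
    in_seg <- t >= starts[seg] & t < ends[seg]
    if (seg == 5) in_seg <- t >= starts[seg] & t <= ends[seg] + 1e-9
    if (!any(in_seg)) next
    p0 <- waypoints[[seg]]; p1 <- waypoints[[seg + 1]]
    vec <- p1 - p0; len <- sqrt(sum(vec^2))
    if (len == 0) { # drinking pause
      hand[in_seg, ] <- matrix(rep(p0, each = sum(in_seg)), ncol = 3)
      next
    }
    e <- vec / len
    tr <- seg_to_transport[seg]
    subs <- spec$submovements[spec$submovements$phase %in% tr, , drop = FALSE]
    prof <- phase_profile(t[in_seg] - starts[seg], d[seg], len, subs)
    hand[in_seg, ] <- matrix(rep(p0, each = sum(in_seg)), ncol = 3) +
      outer(prof$pos, e)
    hand_speed_true[in_seg] <- prof$vel
  }
  after <- t > ends[5]
  hand[after, ] <- matrix(rep(hand0, each = sum(after)), ncol = 3)

  # cup: parked until grasped, moves with the hand, parked after release
  cup <- matrix(rep(cup0, each = n), n, 3)
  held <- t >= starts[2] & t <= ends[4]
  cup[held, ] <- hand[held, ]
  cup_speed_true <- ifelse(held, hand_speed_true, 0)
  cup_speed_true[t >= starts[3] & t < ends[3]] <- 0

  # trunk: forward excursion during transport, hold through the drink
  trunk_base <- c(-150, 0, 400)
  w <- numeric(n)
  w[t >= starts[2] & t < ends[2]] <-
    mj_pos_shape((t[t >= starts[2] & t < ends[2]] - starts[2]) / d[2])
  w[t >= starts[3] & t < ends[3]] <- 1
  w[t >= starts[4] & t < ends[4]] <-
    1 - mj_pos_shape((t[t >= starts[4] & t < ends[4]] - starts[4]) / d[4])
  trunk <- matrix(rep(trunk_base, each = n), n, 3)
  trunk[, 1] <- trunk[, 1] + spec$trunk_excursion * w

  markers <- list(hand = hand, cup = cup, trunk = trunk)
  if (spec$noise_sd > 0) {
    markers <- withr_seed(spec$seed, {
      lapply(markers, function(m) m + matrix(rnorm(3 * n, 0, spec$noise_sd),
                                             n, 3))
    })
  }
  traj <- marker_trajectory(markers, fs, forward_axis = "X",
                            vertical_axis = "Z",
                            participant_id = spec$participant_id,
                            trial_id = spec$trial_id,
                            meta = list(synthetic = TRUE, seed = spec$seed))

  # --- ground truth from the noiseless analytic profiles ---
  hx <- threshold_crossing_times(hand_speed_true, fs)
  onset_gt <- hx[["first"]]; offset_gt <- hx[["last"]]
  cup_thr <- 0.02 * max(cup_speed_true)
  cup_above <- cup_speed_true > cup_thr
  runs <- logical_runs(cup_above)
  bouts <- runs[runs$value, , drop = FALSE]
  boundaries_gt <- c(
    reach_end = (bouts$start[1] - 1) / fs,
    drink_start = (bouts$end[1] - 1) / fs,
    drink_end = (bouts$start[nrow(bouts)] - 1) / fs,
    back_end = (bouts$end[nrow(bouts)] - 1) / fs)

  subs <- spec$submovements
  qualifying <- logical(nrow(subs))
  if (nrow(subs) > 0) {
    transport_starts <- starts[c(1, 2, 4, 5)]
    transport_durs <- d[c(1, 2, 4, 5)]
    peak_times <- transport_starts[subs$phase] + subs$at + subs$width / 2
    for (ph in 1:4) {
      in_ph <- which(subs$phase == ph)
      if (!length(in_ph)) next
      accepted_peaks <- transport_starts[ph] + transport_durs[ph] / 2
      for (k in in_ph[order(-subs$amplitude[in_ph])]) {
        ok <- subs$amplitude[k] > 20 &&
          all(abs(peak_times[k] - accepted_peaks) >= 0.150)
        qualifying[k] <- ok
        if (ok) accepted_peaks <- c(accepted_peaks, peak_times[k])
      }
    }
  }
  # authoritative unit count: the excursion rule applied to the noiseless
  # analytic speed (no filtering/differentiation) within the true windows
  gt_windows <- rbind(
    c(onset_gt, boundaries_gt[["reach_end"]]),
    c(boundaries_gt[["reach_end"]], boundaries_gt[["drink_start"]]),
    c(boundaries_gt[["drink_end"]], boundaries_gt[["back_end"]]),
    c(boundaries_gt[["back_end"]], offset_gt))
  units_per_phase <- vapply(seq_len(4), function(ph) {
    i0 <- 1L + round(gt_windows[ph, 1] * fs)
    i1 <- 1L + round(gt_windows[ph, 2] * fs)
    as.integer(count_units_in_window(hand_speed_true[i0:i1], fs, 20, 150))
  }, integer(1))
  names(units_per_phase) <- c("reaching", "forward_transport",
                              "back_transport", "returning")

  ground_truth <- list(
    onset = onset_gt, offset = offset_gt,
    movement_time = offset_gt - onset_gt,
    boundaries = boundaries_gt,
    n_movement_units = sum(units_per_phase),
    units_per_phase = units_per_phase,
    qualifying_submovements = qualifying,
    trunk_displacement = spec$trunk_excursion / 10,
    peak_hand_speed = max(hand_speed_true),
    hand_speed = hand_speed_true, cup_speed = cup_speed_true)
  list(trajectory = traj, ground_truth = ground_truth)
}

#' Specification of a synthetic A-B-A assessment series
#'
#' Linear-model generator for repeated single-case assessments:
#' `value(session) = baseline_level + baseline_trend * session
#' + effect_shift (in B and A2) + intervention_trend * (position in B)
#' + noise`, rounded to the instrument grid and clipped to the
#' instrument range when an outcome is named.
#'
#' @param n_per_phase counts of sessions in A1, B, A2 (each >= 1).
#' @param baseline_level level at session 0.
#' @param baseline_trend per-session drift present in every phase.
#' @param effect_shift level change added in the B and A2 phases.
#' @param intervention_trend additional per-session trend within B.
#' @param noise_sd Gaussian noise sd.
#' @param value_grid rounding grid (e.g. 1 for integer clinical scores,
#'   0.1 for kinematic outcomes); `NULL` for no rounding.
#' @param outcome optional outcome name; when given, values are clipped
#'   to the instrument range and an [assessment_series()] is returned.
#' @param participant participant identifier.
#' @param seed integer seed.
#' @return object of class `synthetic_series_spec`.
#' @export
synthetic_series_spec <- function(n_per_phase = c(A1 = 5, B = 6, A2 = 5),
                                  baseline_level = 20, baseline_trend = 0,
                                  effect_shift = 0, intervention_trend = 0,
                                  noise_sd = 1, value_grid = NULL,
                                  outcome = NULL, participant = "SYN",
                                  seed = 1L) {
  if (length(n_per_phase) != 3 || any(n_per_phase < 1)) {
    abort("n_per_phase must give >= 1 session for each of A1, B, A2",
          class = "scedrink_invalid_input")
  }
  if (noise_sd < 0) {
    abort("noise_sd must be >= 0", class = "scedrink_invalid_input")
  }
  if (!is.null(outcome)) {
    outcome <- match.arg(outcome, KNOWN_OUTCOMES)
    if (outcome %in% c("fma_ue", "arat") && !is.null(value_grid) &&
        (value_grid != round(value_grid) || value_grid < 1)) {
      abort(sprintf("value grid %g is incompatible with the integer scale of %s",
                    value_grid, outcome),
            class = "scedrink_config_error")
    }
  }
  structure(list(n_per_phase = as.integer(n_per_phase),
                 baseline_level = baseline_level,
                 baseline_trend = baseline_trend,
                 effect_shift = effect_shift,
                 intervention_trend = intervention_trend,
                 noise_sd = noise_sd, value_grid = value_grid,
                 outcome = outcome, participant = participant,
                 seed = as.integer(seed)),
            class = "synthetic_series_spec")
}

#' Generate a synthetic A-B-A assessment series
#'
#' @param spec a [synthetic_series_spec()].
#' @return list with `series` (an [assessment_series()] when the spec
#'   names an outcome, otherwise a tibble of `session`, `phase`, `value`),
#'   `true_values` (the noiseless signal) and the spec itself.
#' @export
generate_series <- function(spec) {
  stopifnot(inherits(spec, "synthetic_series_spec"))
  np <- spec$n_per_phase
  n <- sum(np)
  session <- seq_len(n)
  phase <- rep(c("A1", "B", "A2"), np)
  b_pos <- cumsum(phase == "B") * (phase == "B")
  signal <- spec$baseline_level + spec$baseline_trend * session +
    spec$effect_shift * (phase %in% c("B", "A2")) +
    spec$intervention_trend * b_pos
  value <- signal + if (spec$noise_sd > 0) {
    withr_seed(spec$seed, rnorm(n, 0, spec$noise_sd))
  } else 0
  if (!is.null(spec$value_grid)) {
    value <- round(value / spec$value_grid) * spec$value_grid
  }
  if (!is.null(spec$outcome)) {
    rng <- switch(spec$outcome, fma_ue = c(0, 66), arat = c(0, 57),
                  c(0, Inf))
    value <- pmin(pmax(value, rng[1]), rng[2])
    series <- assessment_series(spec$participant, spec$outcome,
                                session, phase, value)
  } else {
    series <- tibble::tibble(session = session, phase = phase, value = value)
  }
  list(series = series, true_values = signal, spec = spec)
}

#' Simulate a whole multi-participant A-B-A study
#'
#' Builds assessment series for the six study outcomes across participants,
#' with programmed improvements on every outcome (higher clinical scores,
#' faster/smoother/less-compensated drinking task). Participants listed in
#' `kinematic_participants` get the three kinematic outcome series; the
#' others mimic patients unable to complete the drinking task.
#'
#' @param n_participants number of participants.
#' @param n_per_phase sessions per phase (A1, B, A2).
#' @param kinematic_participants indices of participants with drinking-task
#'   data (default: all).
#' @param seed integer seed; per-series seeds are derived from it.
#' @return list of [assessment_series()], named `participant.outcome`.
#' @export
simulate_study <- function(n_participants = 6,
                           n_per_phase = c(A1 = 5, B = 6, A2 = 5),
                           kinematic_participants = seq_len(n_participants),
                           seed = 1L) {
  presets <- list(
    fma_ue = list(level = 20, shift = 8, sd = 1.2, grid = 1),
    arat = list(level = 15, shift = 5, sd = 1.5, grid = 1),
    grip_strength = list(level = 30, shift = 9, sd = 2.5, grid = 0.1),
    movement_time = list(level = 12, shift = -4, sd = 0.8, grid = 0.1),
    movement_units = list(level = 25, shift = -9, sd = 2, grid = 1),
    trunk_displacement = list(level = 8, shift = -2.5, sd = 0.8, grid = 0.1))
  out <- list()
  for (p in seq_len(n_participants)) {
    pid <- sprintf("P%d", p)
    for (oc in names(presets)) {
      kin <- oc %in% c("movement_time", "movement_units", "trunk_displacement")
      if (kin && !p %in% kinematic_participants) next
      pr <- presets[[oc]]
      sp <- synthetic_series_spec(
        n_per_phase = n_per_phase,
        baseline_level = pr$level + 2 * p, baseline_trend = 0,
        effect_shift = pr$shift, intervention_trend = 0,
        noise_sd = pr$sd, value_grid = pr$grid, outcome = oc,
        participant = pid,
        seed = seed + 1000L * p + 10L * match(oc, names(presets)))
      out[[paste(pid, oc, sep = ".")]] <- generate_series(sp)$series
    }
  }
  out
}
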