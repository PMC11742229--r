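#' Construct a marker trajectory object
#'
#' Uniformly sampled 3D marker coordinates (mm) of one drinking-task trial
#' in a lab frame with declared forward (sagittal) and vertical axes.
#' The drinking task requires at least a hand and a trunk marker; phase
#' segmentation additionally uses the cup marker when present.
#'
#' @param markers named list of n x 3 numeric matrices (columns X, Y, Z),
#'   all with the same number of rows; must include `hand` and `trunk`.
#' @param sampling_rate sampling frequency in Hz.
#' @param forward_axis,vertical_axis which coordinate column ("X", "Y" or
#'   "Z") points forward in the sagittal plane / vertically up.
#' @param participant_id,trial_id identifiers carried through to reports.
#' @param meta optional named list of free-form trial metadata (e.g. task
#'   modifications such as a bottle instead of a cup, or a shortened reach
#'   distance); recorded, never used algorithmically.
#' @return object of class `marker_trajectory`.
#' @export
marker_trajectory <- function(markers, sampling_rate,
                              forward_axis = "X", vertical_axis = "Z",
                              participant_id = NA_character_,
                              trial_id = NA_character_, meta = list()) {
  if (!is.list(markers) || is.null(names(markers))) {
    abort("`markers` must be a named list of n x 3 matrices",
          class = "scedrink_invalid_input")
  }
  for (req in c("hand", "trunk")) {
    if (!req %in% names(markers)) {
      abort(sprintf("required marker '%s' is missing", req),
            class = "scedrink_invalid_input")
    }
  }
  n <- nrow(markers[[1]])
  for (nm in names(markers)) {
    m <- as.matrix(markers[[nm]])
    if (ncol(m) != 3 || nrow(m) != n) {
      abort(sprintf("marker '%s' must be an n x 3 matrix (n = %d)", nm, n),
            class = "scedrink_invalid_input")
    }
    if (!all(is.finite(m))) {
      abort(sprintf("marker '%s' has non-finite coordinates after gap handling",
                    nm), class = "scedrink_invalid_input")
    }
    colnames(m) <- c("X", "Y", "Z")
    markers[[nm]] <- m
  }
  if (n < 2 || sampling_rate <= 0) {
    abort("trajectory needs >= 2 frames and a positive sampling rate",
          class = "scedrink_invalid_input")
  }
  forward_axis <- match.arg(forward_axis, c("X", "Y", "Z"))
  vertical_axis <- match.arg(vertical_axis, c("X", "Y", "Z"))
  structure(list(markers = markers, sampling_rate = sampling_rate,
                 n_frames = n, forward_axis = forward_axis,
                 vertical_axis = vertical_axis,
                 participant_id = participant_id, trial_id = trial_id,
                 meta = meta),
            class = "marker_trajectory")
}

#' @export
print.marker_trajectory <- function(x, ...) {
  cat(sprintf(
    "<marker_trajectory> %s/%s: %d frames @ %g Hz (%.2f s), markers: %s\n",
    x$participant_id, x$trial_id, x$n_frames, x$sampling_rate,
    x$n_frames / x$sampling_rate, paste(names(x$markers), collapse = ", ")))
  invisible(x)
}

lowpass_filtfilt <- function(x, sampling_rate, cutoff) {
  if (cutoff >= sampling_rate / 2) {
    abort(sprintf("filter cutoff %g Hz is at or above Nyquist (%g Hz)",
                  cutoff, sampling_rate / 2),
          class = "scedrink_config_error")
  }
  bf <- signal::butter(2, cutoff / (sampling_rate / 2), type = "low")
  # reflect the signal at both ends before the forward-backward pass so
  # that non-zero endpoint levels do not cause filter edge transients
  n <- length(x)
  k <- min(n - 1, max(12L, ceiling(3 * sampling_rate / cutoff)))
  head_pad <- 2 * x[1] - x[(k + 1):2]
  tail_pad <- 2 * x[n] - x[(n - 1):(n - k)]
  y <- signal::filtfilt(bf, c(head_pad, x, tail_pad))
  y[(k + 1):(k + n)]
}

central_diff <- function(x, dt) {
  n <- length(x)
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d[1] <- (x[2] - x[1]) / dt
  d[n] <- (x[n] - x[n - 1]) / dt
  d
}

#' Tangential marker speed
#'
#' Euclidean norm of the time derivative of the low-pass-filtered 3D
#' position of one marker. Filtering is zero-phase (forward-backward
#' second-order Butterworth) so peak timings are not shifted;
#' differentiation uses central differences.
#'
#' @param traj a [marker_trajectory()].
#' @param marker marker name (default `"hand"`).
#' @param cutoff low-pass cutoff in Hz (default 6, standard for reach
#'   kinematics); must be below Nyquist. `NA` skips filtering.
#' @return numeric vector of speeds in mm/s, one per frame.
#' @export
hand_speed <- function(traj, marker = "hand", cutoff = 6) {
  stopifnot(inherits(traj, "marker_trajectory"))
  if (!marker %in% names(traj$markers)) {
    abort(sprintf("marker '%s' not present in trajectory", marker),
          class = "scedrink_invalid_input")
  }
  pos <- traj$markers[[marker]]
  if (!is.na(cutoff)) {
    pos <- apply(pos, 2, lowpass_filtfilt,
                 sampling_rate = traj$sampling_rate, cutoff = cutoff)
  }
  dt <- 1 / traj$sampling_rate
  vel <- apply(pos, 2, central_diff, dt = dt)
  sqrt(rowSums(vel^2))
}

# runs of a logical vector as (start, end, value) rows
logical_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  data.frame(start = ends - r$lengths + 1, end = ends, value = r$values)
}

#' Detect movement onset and offset of a drinking trial
#'
#' Onset is the first time the hand speed exceeds the onset fraction
#' (default 2%) of its peak and stays above it for the sustain window;
#' offset is the last time, searching backward, at which the speed falls
#' below that threshold while the hand is within the return tolerance of
#' its onset position ("back at the initial position"). If the hand never
#' returns within tolerance the offset falls back to the final
#' sub-threshold crossing and `returned_to_start` is `FALSE`.
#'
#' @param speed speed series in mm/s (see [hand_speed()]).
#' @param positions n x 3 matrix of (unfiltered or filtered) hand
#'   positions in mm, same length as `speed`.
#' @param sampling_rate Hz.
#' @param onset_fraction fraction of peak speed (default 0.02).
#' @param sustain_ms minimum time above threshold for a valid onset
#'   (default 50 ms, below the 150 ms movement-unit separation so it
#'   cannot mask a real submovement).
#' @param return_tolerance_mm radius around the onset position within
#'   which the hand counts as "back at the initial position" (default 20).
#' @return list: `onset_frame`, `offset_frame`, `onset`, `offset` (s,
#'   zero-based times), `movement_time` (s), `threshold` (mm/s),
#'   `returned_to_start` (logical).
#' @export
detect_onset_offset <- function(speed, positions, sampling_rate,
                                onset_fraction = 0.02, sustain_ms = 50,
                                return_tolerance_mm = 20) {
  n <- length(speed)
  positions <- as.matrix(positions)
  stopifnot(nrow(positions) == n)
  peak <- max(speed)
  thr <- onset_fraction * peak
  if (!is.finite(peak) || peak <= 0 || !any(speed > thr)) {
    abort("no movement detected: speed never exceeds the onset threshold",
          class = "scedrink_invalid_input")
  }
  sustain_n <- max(1L, round(sustain_ms / 1000 * sampling_rate))
  runs <- logical_runs(speed > thr)
  # a run can anchor onset/offset only if it sustains the threshold and
  # belongs to actual movement (reaches 10% of peak), not a noise blip
  up <- runs[runs$value & (runs$end - runs$start + 1) >= sustain_n, ,
             drop = FALSE]
  if (nrow(up) > 0) {
    run_peak <- vapply(seq_len(nrow(up)), function(i)
      max(speed[up$start[i]:up$end[i]]), numeric(1))
    up <- up[run_peak >= 0.10 * peak, , drop = FALSE]
  }
  if (nrow(up) == 0) {
    abort("no movement detected: threshold never sustained",
          class = "scedrink_invalid_input")
  }
  onset_frame <- up$start[1]
  start_pos <- positions[onset_frame, ]
  dist_from_start <- sqrt(colSums((t(positions) - start_pos)^2))

  # down-crossings at the end of movement runs, scanned backward
  candidates <- rev(pmin(up$end + 1L, n))
  returned <- TRUE
  near <- dist_from_start[candidates] <= return_tolerance_mm
  if (any(near)) {
    offset_frame <- candidates[which(near)[1]]
  } else {
    offset_frame <- candidates[1]
    returned <- FALSE
  }
  if (!returned) {
    warn("hand did not return within tolerance of its starting position; offset fell back to the final sub-threshold crossing",
         class = "scedrink_offset_fallback")
  }
  list(onset_frame = onset_frame, offset_frame = offset_frame,
       onset = (onset_frame - 1) / sampling_rate,
       offset = (offset_frame - 1) / sampling_rate,
       movement_time = (offset_frame - onset_frame) / sampling_rate,
       threshold = thr, returned_to_start = returned)
}

#' Segment a drinking trial into its five phases
#'
#' Splits the interval between onset and offset into reaching, forward
#' transport, drinking, back transport and returning, using the cup
#' marker: the cup is stationary except during the two transport phases,
#' so the two sustained bouts in which the cup speed exceeds 2% of its
#' peak delimit forward transport (reaching ends when the cup starts
#' moving) and back transport (returning starts when the cup is replaced).
#' The drinking pause is the interval between the bouts; the maximal cup
#' elevation is checked to fall inside it. Alternatively, explicit
#' boundary annotations can be supplied and are returned verbatim after
#' ordering validation.
#'
#' @param traj a [marker_trajectory()] with a `cup` marker (unless
#'   `annotations` is given).
#' @param onset,offset trial onset/offset in seconds
#'   (from [detect_onset_offset()]).
#' @param cutoff low-pass cutoff for the cup speed (Hz).
#' @param onset_fraction fraction of the peak cup speed delimiting cup
#'   motion (default 0.02).
#' @param min_bout_ms minimum duration of a cup-motion bout (default
#'   100 ms; rejects noise blips).
#' @param annotations optional numeric vector of the four interior
#'   boundaries (s): end of reaching, start of drinking, end of drinking,
#'   end of back transport.
#' @return object of class `phase_segmentation`: `onset`, `boundaries`
#'   (named numeric: `reach_end`, `drink_start`, `drink_end`,
#'   `back_end`), `offset`, all in seconds.
#' @export
segment_phases <- function(traj, onset, offset, cutoff = 6,
                           onset_fraction = 0.02, min_bout_ms = 100,
                           annotations = NULL) {
  if (!is.null(annotations)) {
    b <- as.numeric(annotations)
    if (length(b) != 4) {
      abort("annotations must give exactly 4 interior boundaries",
            class = "scedrink_invalid_input")
    }
    return(new_segmentation(onset, b, offset))
  }
  stopifnot(inherits(traj, "marker_trajectory"))
  if (!"cup" %in% names(traj$markers)) {
    abort("phase segmentation needs a 'cup' marker or explicit boundary annotations",
          class = "scedrink_invalid_input")
  }
  fs <- traj$sampling_rate
  cs <- hand_speed(traj, marker = "cup", cutoff = cutoff)
  i0 <- max(1L, 1L + round(onset * fs))
  i1 <- min(length(cs), 1L + round(offset * fs))
  win <- i0:i1
  peak <- max(cs[win])
  thr <- onset_fraction * peak
  if (peak <= 0 || !any(cs[win] > thr)) {
    abort("cup never moves: cannot segment the transport phases",
          class = "scedrink_invalid_input")
  }
  min_bout_n <- max(1L, round(min_bout_ms / 1000 * fs))
  s <- cs[win]
  # two-threshold bout detection: cores must clear 20% of the peak
  # (unreachable by marker noise), boundaries are the 2% crossings
  cores <- logical_runs(s > 0.2 * peak)
  cores <- cores[cores$value & (cores$end - cores$start + 1) >= min_bout_n, ,
                 drop = FALSE]
  if (nrow(cores) < 2) {
    abort("expected two cup-transport bouts (forward and back) but found fewer",
          class = "scedrink_invalid_input")
  }
  # the longest cup rest between cores is the drinking pause; cores before
  # it belong to the forward transport, cores after it to the back transport
  gaps <- cores$start[-1] - cores$end[-nrow(cores)]
  split <- which.max(gaps)
  extend_left <- function(i) { while (i > 1 && s[i - 1] > thr) i <- i - 1; i }
  extend_right <- function(i) {
    while (i < length(s) && s[i + 1] > thr) i <- i + 1
    i
  }
  to_time <- function(local_idx) (win[1] - 1 + local_idx - 1) / fs
  b <- c(to_time(extend_left(cores$start[1])),
         to_time(extend_right(cores$end[split])),
         to_time(extend_left(cores$start[split + 1])),
         to_time(extend_right(cores$end[nrow(cores)])))
  seg <- new_segmentation(onset, b, offset)

  # sanity: the cup's maximal elevation should occur at/inside the pause
  z <- traj$markers$cup[win, traj$vertical_axis]
  t_zmax <- to_time(which.max(z))
  if (t_zmax < b[1] || t_zmax > b[3] + 2 / fs) {
    warn("maximal cup elevation lies outside the detected drinking interval",
         class = "scedrink_segmentation_warning")
  }
  seg
}

new_segmentation <- function(onset, b, offset) {
  times <- c(onset, b, offset)
  if (any(diff(times) <= 0)) {
    abort(sprintf(
      "phase boundaries must be strictly ordered within [onset, offset]: %s",
      paste(signif(times, 4), collapse = " < ")),
      class = "scedrink_invalid_input")
  }
  structure(list(onset = onset,
                 boundaries = c(reach_end = b[1], drink_start = b[2],
                                drink_end = b[3], back_end = b[4]),
                 offset = offset),
            class = "phase_segmentation")
}

#' @export
print.phase_segmentation <- function(x, ...) {
  cat(sprintf(
    "<phase_segmentation> onset %.3f | reach %.3f | forward %.3f | drink %.3f | back %.3f | return %.3f s\n",
    x$onset, x$boundaries[1], x$boundaries[2], x$boundaries[3],
    x$boundaries[4], x$offset))
  invisible(x)
}

transport_windows <- function(seg, sampling_rate, n) {
  idx <- function(t) min(n, max(1L, 1L + round(t * sampling_rate)))
  b <- seg$boundaries
  list(reaching = c(idx(seg$onset), idx(b[["reach_end"]])),
       forward_transport = c(idx(b[["reach_end"]]), idx(b[["drink_start"]])),
       back_transport = c(idx(b[["drink_end"]]), idx(b[["back_end"]])),
       returning = c(idx(b[["back_end"]]), idx(seg$offset)))
}

count_units_in_window <- function(s, sampling_rate, amplitude_limit,
                                  min_peak_separation) {
  n <- length(s)
  if (n < 3) return(0L)
  rising <- s[-1] > s[-n]
  # local maxima: strictly above the previous sample, not below the next
  is_max <- c(FALSE, rising) & c(s[-n] >= s[-1], TRUE)
  is_max[c(1, n)] <- FALSE
  peaks <- which(is_max)
  if (length(peaks) == 0) return(0L)
  # local minima (incl. the window start as implicit trough)
  is_min <- c(FALSE, !rising) & c(s[-n] <= s[-1], TRUE)
  troughs <- sort(unique(c(1L, which(is_min))))
  amp <- vapply(peaks, function(p) {
    t_prev <- max(troughs[troughs < p])
    s[p] - min(s[t_prev:p])
  }, numeric(1))
  cand <- peaks[amp > amplitude_limit]
  camp <- amp[amp > amplitude_limit]
  if (length(cand) == 0) return(0L)
  # enforce the minimum peak separation, keeping the larger-amplitude peak
  sep_frames <- min_peak_separation / 1000 * sampling_rate
  ord <- order(-camp, cand)
  accepted <- integer(0)
  for (k in ord) {
    if (all(abs(cand[k] - accepted) >= sep_frames)) {
      accepted <- c(accepted, cand[k])
    }
  }
  length(accepted)
}

#' Count movement units over the four transport phases
#'
#' A movement unit is a local-minimum-to-next-local-maximum excursion of
#' the hand speed profile whose amplitude exceeds 20 mm/s, with accepted
#' velocity peaks at least 150 ms apart (when two peaks conflict, the
#' larger-amplitude one is kept). Units are counted within each of the
#' four transport phases (reaching, forward transport, back transport,
#' returning); the drinking pause contributes nothing. The count indexes
#' movement smoothness: a completed drinking task has at least 4 units.
#'
#' @param speed hand speed series in mm/s.
#' @param segmentation a [segment_phases()] result.
#' @param sampling_rate Hz.
#' @param amplitude_limit minimum excursion amplitude in mm/s (default 20).
#' @param min_peak_separation minimum time between accepted peaks in ms
#'   (default 150).
#' @return list: `n_movement_units` (integer total), `units_per_phase`
#'   (named integer vector over the four transport phases).
#' @export
count_movement_units <- function(speed, segmentation, sampling_rate,
                                 amplitude_limit = 20,
                                 min_peak_separation = 150) {
  stopifnot(inherits(segmentation, "phase_segmentation"))
  if (amplitude_limit <= 0 || min_peak_separation <= 0) {
    abort("amplitude_limit and min_peak_separation must be positive",
          class = "scedrink_config_error")
  }
  wins <- transport_windows(segmentation, sampling_rate, length(speed))
  units <- vapply(names(wins), function(ph) {
    w <- wins[[ph]]
    if (w[2] - w[1] < 1) {
      warn(sprintf("transport phase '%s' is shorter than 2 frames; counting 0 units",
                   ph), class = "scedrink_short_phase")
      return(0L)
    }
    as.integer(count_units_in_window(speed[w[1]:w[2]], sampling_rate,
                                     amplitude_limit, min_peak_separation))
  }, integer(1))
  list(n_movement_units = sum(units), units_per_phase = units)
}

#' Maximal forward trunk displacement
#'
#' Maximum forward (sagittal-axis) excursion of the trunk marker between
#' onset and offset, relative to its position at onset, floored at zero
#' and reported in cm. Quantifies compensatory trunk movement during the
#' drinking task.
#'
#' @param traj a [marker_trajectory()] with a `trunk` marker and a
#'   declared forward axis.
#' @param onset,offset trial onset/offset in seconds.
#' @return displacement in cm (>= 0).
#' @export
trunk_displacement <- function(traj, onset, offset) {
  stopifnot(inherits(traj, "marker_trajectory"))
  fs <- traj$sampling_rate
  fwd <- traj$markers$trunk[, traj$forward_axis]
  i0 <- max(1L, 1L + round(onset * fs))
  i1 <- min(length(fwd), 1L + round(offset * fs))
  max(0, max(fwd[i0:i1] - fwd[i0])) / 10
}

#' Extract all kinematic metrics from one drinking trial
#'
#' Convenience wrapper running the full per-trial pipeline: filtered hand
#' speed, onset/offset detection, phase segmentation, movement-unit
#' counting and trunk displacement.
#'
#' @param traj a [marker_trajectory()].
#' @param config a [study_config()] (its `kinematics` block supplies the
#'   filter cutoff and all thresholds).
#' @param annotations optional phase-boundary annotations passed to
#'   [segment_phases()].
#' @return object of class `trial_kinematics`: `movement_time` (s),
#'   `n_movement_units`, `units_per_phase`, `trunk_displacement` (cm),
#'   `peak_hand_speed` (mm/s), `onset`, `offset`, `segmentation`,
#'   `returned_to_start`, plus the trial identifiers.
#' @export
trial_kinematics <- function(traj, config = study_config(),
                             annotations = NULL) {
  k <- config$kinematics
  sp <- hand_speed(traj, "hand", cutoff = k$filter_cutoff)
  oo <- detect_onset_offset(sp, traj$markers$hand, traj$sampling_rate,
                            onset_fraction = k$onset_fraction,
                            sustain_ms = k$sustain_ms,
                            return_tolerance_mm = k$return_tolerance)
  seg <- segment_phases(traj, oo$onset, oo$offset, cutoff = k$filter_cutoff,
                        onset_fraction = k$onset_fraction,
                        min_bout_ms = k$min_bout_ms,
                        annotations = annotations)
  mu <- count_movement_units(sp, seg, traj$sampling_rate,
                             amplitude_limit = k$amplitude_limit,
                             min_peak_separation = k$min_peak_separation)
  structure(
    list(participant_id = traj$participant_id, trial_id = traj$trial_id,
         movement_time = oo$movement_time,
         n_movement_units = mu$n_movement_units,
         units_per_phase = mu$units_per_phase,
         trunk_displacement = trunk_displacement(traj, oo$onset, oo$offset),
         peak_hand_speed = max(sp),
         onset = oo$onset, offset = oo$offset, segmentation = seg,
         returned_to_start = oo$returned_to_start),
    class = "trial_kinematics")
}

#' @export
print.trial_kinematics <- function(x, ...) {
  cat(sprintf(
    "<trial_kinematics> %s/%s: MT %.2f s, %d movement units (%s), trunk %.1f cm, peak %.0f mm/s\n",
    x$participant_id, x$trial_id, x$movement_time, x$n_movement_units,
    paste(x$units_per_phase, collapse = "+"), x$trunk_displacement,
    x$peak_hand_speed))
  invisible(x)
}

#' Aggregate repeated trials of one assessment session
#'
#' At least five successful trials per arm are collected per session; this
#' reduces them to one value per metric. Both the mean and the median are
#' reported; the configured statistic (default mean) is the one fed into
#' the assessment series for the single-case statistics.
#'
#' @param trials list of [trial_kinematics()] results (>= 1).
#' @param statistic `"mean"` or `"median"`.
#' @return one-row tibble with `n_trials`, mean and median of each metric,
#'   and `movement_time`, `movement_units`, `trunk_displacement` set to
#'   the configured statistic.
#' @export
aggregate_trials <- function(trials, statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  if (length(trials) == 0) {
    abort("no trials to aggregate", class = "scedrink_invalid_input")
  }
  stopifnot(all(vapply(trials, inherits, logical(1), "trial_kinematics")))
  g <- function(f) vapply(trials, function(t) as.numeric(t[[f]]), numeric(1))
  pick <- function(x) if (statistic == "mean") mean(x) else median(x)
  mt <- g("movement_time"); mu <- g("n_movement_units")
  td <- g("trunk_displacement")
  tibble::tibble(
    n_trials = length(trials), statistic = statistic,
    movement_time_mean = mean(mt), movement_time_median = median(mt),
    movement_units_mean = mean(mu), movement_units_median = median(mu),
    trunk_displacement_mean = mean(td), trunk_displacement_median = median(td),
    movement_time = pick(mt), movement_units = pick(mu),
    trunk_displacement = pick(td))
}
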