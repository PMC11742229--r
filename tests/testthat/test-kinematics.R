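make_traj <- function(hand, cup = NULL, trunk = NULL, fs = 240) {
  n <- nrow(hand)
  if (is.null(trunk)) trunk <- matrix(rep(c(-150, 0, 400), each = n), n, 3)
  m <- list(hand = hand, trunk = trunk)
  if (!is.null(cup)) m$cup <- cup
  marker_trajectory(m, fs)
}

test_that("hand_speed recovers analytic speeds", {
  n <- 480
  still <- make_traj(matrix(0, n, 3))
  expect_true(all(hand_speed(still) < 1e-8))

  # straight-line motion at 100 mm/s
  t <- (0:(n - 1)) / 240
  mov <- make_traj(cbind(100 * t, 0, 0))
  sp <- hand_speed(mov)
  mid <- sp[100:380]
  expect_equal(mean(mid), 100, tolerance = 1e-3)

  # minimum-jerk segment: peak speed 1.875 * A / T
  seg <- minimum_jerk_segment(1, 300, 240)
  expect_equal(max(seg$speed), 1.875 * 300, tolerance = 1e-3)
  pad <- matrix(0, 120, 3)
  end_pad <- matrix(rep(c(300, 0, 0), each = 120), 120, 3)
  pos <- rbind(pad, cbind(seg$position, 0, 0), end_pad)
  tr <- make_traj(pos)
  expect_equal(max(hand_speed(tr)), 562.5, tolerance = 0.01 * 562.5)

  expect_error(hand_speed(still, marker = "cup"),
               class = "scedrink_invalid_input")
  expect_error(hand_speed(still, cutoff = 200),
               class = "scedrink_config_error")
})

test_that("speed integrates back to the movement amplitude", {
  seg <- minimum_jerk_segment(1.4, 250, 240)
  expect_equal(sum(seg$speed) / 240, 250, tolerance = 1e-3)
  expect_error(minimum_jerk_segment(1, 0), class = "scedrink_invalid_input")
  expect_error(minimum_jerk_segment(-1, 10), class = "scedrink_invalid_input")
})

test_that("onset/offset bracket a programmed out-and-back movement", {
  tr <- generate_trial(synthetic_trial_spec(noise_sd = 0))
  sp <- hand_speed(tr$trajectory)
  oo <- detect_onset_offset(sp, tr$trajectory$markers$hand, 240)
  expect_lt(abs(oo$onset - tr$ground_truth$onset), 1.5 / 240)
  expect_lt(abs(oo$offset - tr$ground_truth$offset), 1.5 / 240)
  expect_true(oo$returned_to_start)

  expect_error(detect_onset_offset(rep(0, 100), matrix(0, 100, 3), 240),
               "no movement", class = "scedrink_invalid_input")
})

test_that("offset falls back with a warning when the hand does not return", {
  # truncate the trial before the hand gets back to its start
  tr <- generate_trial(synthetic_trial_spec(noise_sd = 0))
  cut <- round((tr$ground_truth$offset - 0.8) * 240)
  hand <- tr$trajectory$markers$hand[1:cut, ]
  sp <- hand_speed(make_traj(hand))
  expect_warning(
    oo <- detect_onset_offset(sp, hand, 240),
    class = "scedrink_offset_fallback")
  expect_false(oo$returned_to_start)
})

test_that("phase segmentation recovers programmed boundaries", {
  for (durs in list(NULL, slow_durations)) {
    spec <- if (is.null(durs)) synthetic_trial_spec(noise_sd = 0) else
      synthetic_trial_spec(phase_durations = durs, noise_sd = 0)
    tr <- generate_trial(spec)
    tk <- trial_kinematics(tr$trajectory)
    expect_true(all(abs(tk$segmentation$boundaries -
                          tr$ground_truth$boundaries) <= 3 / 240))
  }

  # annotations are honoured verbatim after ordering validation
  tr <- generate_trial(synthetic_trial_spec(noise_sd = 0))
  seg <- segment_phases(tr$trajectory, 0.5, 7.9,
                        annotations = c(2, 3.2, 5.2, 6.4))
  expect_equal(unname(seg$boundaries), c(2, 3.2, 5.2, 6.4))
  expect_error(segment_phases(tr$trajectory, 0.5, 7.9,
                              annotations = c(3.2, 2, 5.2, 6.4)),
               class = "scedrink_invalid_input")

  # no cup marker and no annotations is an error
  no_cup <- marker_trajectory(tr$trajectory$markers[c("hand", "trunk")], 240)
  expect_error(segment_phases(no_cup, 0.5, 7.9), "cup",
               class = "scedrink_invalid_input")

  # degenerate trial without cup motion
  n <- 1200
  flat <- make_traj(cbind(seq(0, 100, length.out = n), 0, 0),
                    cup = matrix(rep(c(300, 0, 0), each = n), n, 3))
  expect_error(segment_phases(flat, 0.2, 4.5),
               class = "scedrink_invalid_input")
})

test_that("a clean trial counts the task minimum of four movement units", {
  tr <- generate_trial(synthetic_trial_spec(noise_sd = 0))
  tk <- trial_kinematics(tr$trajectory)
  expect_identical(tk$n_movement_units, 4L)
  expect_identical(unname(tk$units_per_phase), rep(1L, 4))
})

test_that("qualifying injected submovements are counted, one unit each", {
  sm <- data.frame(phase = c(2, 2), at = c(0.4, 1.6), amplitude = 80,
                   width = 0.2)
  tr <- generate_trial(synthetic_trial_spec(phase_durations = slow_durations,
                                            submovements = sm, noise_sd = 0))
  tk <- trial_kinematics(tr$trajectory)
  # the phase with 2 extra submovements counts 3, total 4 + 2
  expect_identical(unname(tk$units_per_phase[["forward_transport"]]), 3L)
  expect_identical(tk$n_movement_units, 6L)
  expect_identical(tr$ground_truth$n_movement_units, 6L)
  expect_true(all(tr$ground_truth$qualifying_submovements))

  sm3 <- data.frame(phase = c(1, 3, 4), at = c(0.3, 0.5, 1.5),
                    amplitude = c(90, 60, 75), width = 0.2)
  tr3 <- generate_trial(synthetic_trial_spec(phase_durations = slow_durations,
                                             submovements = sm3,
                                             noise_sd = 0))
  tk3 <- trial_kinematics(tr3$trajectory)
  expect_identical(tk3$n_movement_units, 7L)
  expect_identical(tk3$n_movement_units, tr3$ground_truth$n_movement_units)

  # a sub-threshold injection (below the 20 mm/s amplitude limit) does not
  # count and is flagged non-qualifying
  sm0 <- data.frame(phase = 2, at = 0.4, amplitude = 15, width = 0.2)
  tr0 <- generate_trial(synthetic_trial_spec(phase_durations = slow_durations,
                                             submovements = sm0,
                                             noise_sd = 0))
  expect_false(tr0$ground_truth$qualifying_submovements)
  expect_identical(trial_kinematics(tr0$trajectory)$n_movement_units, 4L)
  expect_identical(tr0$ground_truth$n_movement_units, 4L)
})

test_that("sub-threshold ripple leaves the unit count unchanged", {
  tr <- generate_trial(synthetic_trial_spec(phase_durations = slow_durations,
                                            noise_sd = 0))
  tk <- trial_kinematics(tr$trajectory)
  sp <- hand_speed(tr$trajectory)
  t <- (seq_along(sp) - 1) / 240
  # 8 mm/s peak-to-trough at 20 Hz: even riding on the steepest profile
  # slope (~310 mm/s^2, adding ~8 mm/s over a half-period) every excursion
  # stays below the 20 mm/s amplitude limit
  rippled <- sp + 4 * (1 + sin(2 * pi * 20 * t))
  mu <- count_movement_units(rippled, tk$segmentation, 240)
  expect_identical(mu$n_movement_units, tk$n_movement_units)
})

test_that("unit count is monotone in both thresholds", {
  sm <- data.frame(phase = c(2, 2, 3), at = c(0.4, 1.6, 0.7),
                   amplitude = c(80, 40, 60), width = 0.2)
  tr <- generate_trial(synthetic_trial_spec(phase_durations = slow_durations,
                                            submovements = sm,
                                            noise_sd = 0.3, seed = 8))
  tk <- trial_kinematics(tr$trajectory)
  sp <- hand_speed(tr$trajectory)
  prev <- Inf
  for (amp in c(5, 20, 50, 90, 200)) {
    cur <- count_movement_units(sp, tk$segmentation, 240,
                                amplitude_limit = amp)$n_movement_units
    expect_lte(cur, prev); prev <- cur
  }
  prev <- Inf
  for (sep in c(50, 150, 400, 1200)) {
    cur <- count_movement_units(sp, tk$segmentation, 240,
                                min_peak_separation = sep)$n_movement_units
    expect_lte(cur, prev); prev <- cur
  }
  expect_error(count_movement_units(sp, tk$segmentation, 240,
                                    amplitude_limit = -1),
               class = "scedrink_config_error")
})

test_that("trunk displacement is the floored forward excursion in cm", {
  tr <- generate_trial(synthetic_trial_spec(trunk_excursion = 60,
                                            noise_sd = 0))
  tk <- trial_kinematics(tr$trajectory)
  expect_equal(tk$trunk_displacement, 6, tolerance = 0.01)

  # stationary trunk
  tr0 <- generate_trial(synthetic_trial_spec(trunk_excursion = 0,
                                             noise_sd = 0))
  expect_equal(trial_kinematics(tr0$trajectory)$trunk_displacement, 0,
               tolerance = 1e-6)

  # backward-only trunk motion floors at zero
  tr_b <- generate_trial(synthetic_trial_spec(trunk_excursion = -40,
                                              noise_sd = 0))
  expect_equal(trial_kinematics(tr_b$trajectory)$trunk_displacement, 0,
               tolerance = 1e-6)
})

test_that("uniform time scaling scales movement time, not displacement", {
  base <- synthetic_trial_spec(noise_sd = 0, trunk_excursion = 45)
  slow <- synthetic_trial_spec(phase_durations = base$phase_durations * 1.5,
                               noise_sd = 0, trunk_excursion = 45)
  k1 <- trial_kinematics(generate_trial(base)$trajectory)
  k2 <- trial_kinematics(generate_trial(slow)$trajectory)
  expect_equal(k2$movement_time / k1$movement_time, 1.5, tolerance = 0.01)
  expect_equal(k2$trunk_displacement, k1$trunk_displacement,
               tolerance = 0.01)
})

test_that("identical trajectories give bit-identical metrics", {
  t1 <- generate_trial(synthetic_trial_spec(noise_sd = 0.4, seed = 21))
  t2 <- generate_trial(synthetic_trial_spec(noise_sd = 0.4, seed = 21))
  expect_identical(t1$trajectory$markers, t2$trajectory$markers)
  k1 <- trial_kinematics(t1$trajectory)
  k2 <- trial_kinematics(t2$trajectory)
  expect_identical(k1$movement_time, k2$movement_time)
  expect_identical(k1$n_movement_units, k2$n_movement_units)
  expect_identical(k1$trunk_displacement, k2$trunk_displacement)
})

test_that("aggregate_trials reports means and medians over trials", {
  mk <- function(mt) {
    tr <- generate_trial(synthetic_trial_spec(noise_sd = 0))
    k <- trial_kinematics(tr$trajectory)
    k$movement_time <- mt
    k
  }
  trials <- lapply(c(5, 6, 7, 8, 9), mk)
  agg <- aggregate_trials(trials)
  expect_equal(agg$movement_time_mean, 7)
  expect_equal(agg$movement_time_median, 7)
  expect_equal(agg$movement_time, 7)

  # one outlier: median robust, mean shifted, both reported
  out <- aggregate_trials(lapply(c(5, 5, 5, 5, 30), mk))
  expect_equal(out$movement_time_median, 5)
  expect_equal(out$movement_time_mean, 10)

  one <- aggregate_trials(trials[3], statistic = "median")
  expect_equal(one$movement_time, 7)
  expect_error(aggregate_trials(list()), class = "scedrink_invalid_input")
})
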