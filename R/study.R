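KINEMATIC_OUTCOMES <- c("movement_time", "movement_units", "trunk_displacement")

#' Turn per-session drinking trials into assessment series
#'
#' Extracts trial kinematics from every trajectory, aggregates repeated
#' trials of each participant x session with the configured statistic,
#' and assembles one [assessment_series()] per participant for each of
#' the three kinematic outcomes.
#'
#' @param trajectories list of entries, each a list with fields
#'   `trajectory` (a [marker_trajectory()]), `participant`, `session`
#'   (integer ordinal) and `phase` (A1/B/A2/FU label of that assessment
#'   session).
#' @param config a [study_config()].
#' @return named list of [assessment_series()], keys
#'   `"participant.outcome"`.
#' @export
trials_to_series <- function(trajectories, config = study_config()) {
  per_trial <- lapply(trajectories, function(e) {
    tk <- trial_kinematics(e$trajectory, config)
    tibble::tibble(participant = e$participant, session = e$session,
                   phase = e$phase,
                   movement_time = tk$movement_time,
                   movement_units = tk$n_movement_units,
                   trunk_displacement = tk$trunk_displacement)
  })
  df <- dplyr::bind_rows(per_trial)
  agg_fun <- if (config$aggregation == "mean") mean else median
  per_session <- df |>
    dplyr::group_by(.data$participant, .data$session, .data$phase) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(KINEMATIC_OUTCOMES),
                                   agg_fun), .groups = "drop") |>
    dplyr::arrange(.data$participant, .data$session)
  out <- list()
  for (pid in unique(per_session$participant)) {
    rows <- per_session[per_session$participant == pid, ]
    for (oc in KINEMATIC_OUTCOMES) {
      out[[paste(pid, oc, sep = ".")]] <-
        assessment_series(pid, oc, rows$session, rows$phase, rows[[oc]])
    }
  }
  out
}

#' Run the full single-case study analysis
#'
#' For every participant x outcome series: fits the baseline-corrected
#' Tau-U between the A1 and A2 phases (the follow-up phase is excluded
#' from all inferential statistics and retained for descriptives only)
#' and computes the MCID-referenced change report. Kinematic trials, when
#' supplied, are first aggregated per session via [trials_to_series()].
#' Participants who appear in the assessments but have no drinking-task
#' data receive explicit "not assessed" rows for the kinematic outcomes.
#'
#' @param assessments named list of [assessment_series()] (see
#'   [read_assessments()]).
#' @param trajectories optional list of trajectory entries (see
#'   [trials_to_series()]), or `NULL` for a clinical-only report.
#' @param config a [study_config()].
#' @return object of class `study_report`: `effect_sizes` (tibble, one
#'   row per participant x outcome: counts, Tau-U, p-value, method, band,
#'   status), `mcid_changes` (tibble of medians, delta and
#'   percent-of-MCID), `descriptives` (per-phase tibble), and `meta`
#'   (config echo, seed, number of tests, package version).
#' @export
run_study <- function(assessments, trajectories = NULL,
                      config = study_config()) {
  series <- assessments
  if (!is.null(trajectories) && length(trajectories) > 0) {
    kin <- trials_to_series(trajectories, config)
    extra <- setdiff(
      unique(vapply(kin, function(s) s$participant, "")),
      unique(vapply(series, function(s) s$participant, "")))
    if (length(extra)) {
      warn(sprintf("participant(s) %s have kinematic trials but no assessment series",
                   paste(extra, collapse = ", ")))
    }
    series <- c(series, kin)
  }
  participants <- unique(vapply(series, function(s) s$participant, ""))
  have_kin <- any(vapply(series, function(s)
    s$outcome %in% KINEMATIC_OUTCOMES, TRUE))

  es_rows <- list(); ch_rows <- list(); desc_rows <- list()
  n_tests <- 0L
  for (s in series) {
    key <- paste(s$participant, s$outcome, sep = ".")
    a1 <- phase_values(s, "A1"); a2 <- phase_values(s, "A2")
    band <- config$mcid[[s$outcome]]
    if (length(a1) >= 2 && length(a2) >= 1) {
      tu <- tau_u(a1, a2, variant = config$tauu$variant,
                  p_method = config$tauu$p_method,
                  n_permutations = config$tauu$n_permutations,
                  exact_limit = config$tauu$exact_limit,
                  seed = config$tauu$seed)
      n_tests <- n_tests + 1L
      if (tu$exceeds_unit_range) {
        warn(sprintf("%s: |tau_u| = %.3f exceeds 1 (reported unclamped)",
                     key, abs(tu$tau_u)))
      }
      es_rows[[key]] <- tibble::tibble(
        participant = s$participant, outcome = s$outcome,
        n_a1 = tu$n_a, n_a2 = tu$n_b, s_ab = tu$s_ab,
        s_trend_a = tu$s_trend_a, tau_ab = tu$tau_ab, tau_u = tu$tau_u,
        p_value = tu$p_value, p_method = tu$p_method,
        effect_band = tu$effect_band,
        exceeds_unit_range = tu$exceeds_unit_range, status = "analyzed")
    } else {
      es_rows[[key]] <- not_assessed_row(s$participant, s$outcome,
                                         "insufficient A1/A2 data")
    }
    if (length(a1) >= 1 && length(a2) >= 1 && !is.null(band)) {
      ch <- mcid_change(s, band)
      ch_rows[[key]] <- tibble::tibble(
        participant = s$participant, outcome = s$outcome,
        median_a1 = ch$median_a1, median_a2 = ch$median_a2,
        delta = ch$delta, percent_of_mcid = ch$percent_of_mcid,
        reached_lower_mcid = ch$reached_lower_mcid,
        reached_upper_mcid = ch$reached_upper_mcid, status = "analyzed")
    }
    for (ph in intersect(PHASE_LEVELS, unique(s$observations$phase))) {
      desc_rows[[paste(key, ph)]] <- dplyr::mutate(
        phase_descriptives(s, ph),
        participant = s$participant, outcome = s$outcome, .before = 1)
    }
  }
  # explicit "not assessed" kinematic cells for participants without trials
  if (have_kin) {
    keys <- names(series)
    for (pid in participants) {
      for (oc in KINEMATIC_OUTCOMES) {
        key <- paste(pid, oc, sep = ".")
        if (!key %in% keys) {
          es_rows[[key]] <- not_assessed_row(pid, oc, "not assessed")
        }
      }
    }
  }
  structure(list(
    effect_sizes = dplyr::arrange(dplyr::bind_rows(es_rows),
                                  .data$participant, .data$outcome),
    mcid_changes = dplyr::arrange(dplyr::bind_rows(ch_rows),
                                  .data$participant, .data$outcome),
    descriptives = dplyr::bind_rows(desc_rows),
    meta = list(
      tauu = config$tauu, aggregation = config$aggregation,
      kinematics = config$kinematics,
      n_inferential_tests = n_tests,
      multiple_testing_correction = "none",
      package_version = as.character(utils::packageVersion("scedrink")))),
    class = "study_report")
}

not_assessed_row <- function(pid, oc, why) {
  tibble::tibble(participant = pid, outcome = oc,
                 n_a1 = NA_integer_, n_a2 = NA_integer_,
                 s_ab = NA_integer_, s_trend_a = NA_integer_,
                 tau_ab = NA_real_, tau_u = NA_real_, p_value = NA_real_,
                 p_method = NA_character_, effect_band = NA_character_,
                 exceeds_unit_range = NA, status = why)
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d effect-size rows (%d tests, %s correction)\n",
              nrow(x$effect_sizes), x$meta$n_inferential_tests,
              x$meta$multiple_testing_correction))
  print(x$effect_sizes, n = 20)
  invisible(x)
}

#' Write a study report bundle to disk
#'
#' Writes the effect-size table and the percent-of-MCID table as CSV and
#' the full bundle (tables, descriptives, settings, seed, package
#' version) as JSON.
#'
#' @param report a [run_study()] result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$effect_sizes, file.path(dir, "effect_sizes.csv"),
                   row.names = FALSE)
  utils::write.csv(report$mcid_changes, file.path(dir, "mcid_changes.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(effect_sizes = report$effect_sizes,
         mcid_changes = report$mcid_changes,
         descriptives = report$descriptives, meta = report$meta),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}
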