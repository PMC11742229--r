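ASSESSMENT_COLUMNS <- c("participant", "outcome", "phase", "session", "value")

#' Read assessment series from CSV
#'
#' Expects a UTF-8, comma-separated file with header
#' `participant,outcome,phase,session,value` (decimal point). Rows are
#' grouped by participant x outcome, ordered by session, and validated
#' against the series invariants (instrument ranges, strictly increasing
#' sessions, A1 <= B <= A2 <= FU phase order). Malformed rows are
#' reported with their line numbers.
#'
#' @param path CSV file path.
#' @return named list of [assessment_series()], keys
#'   `"participant.outcome"`.
#' @export
read_assessments <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(ASSESSMENT_COLUMNS, names(df))
  if (length(missing_cols)) {
    abort(paste0("assessment file is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "scedrink_invalid_input")
  }
  df$line <- seq_len(nrow(df)) + 1L # header is line 1
  bad <- !df$phase %in% PHASE_LEVELS
  if (any(bad)) {
    abort(sprintf("unknown phase label(s) at line(s) %s",
                  paste(df$line[bad], collapse = ", ")),
          class = "scedrink_invalid_input")
  }
  if (!is.numeric(df$value) || !is.numeric(df$session)) {
    abort("`session` and `value` must be numeric",
          class = "scedrink_invalid_input")
  }
  keys <- paste(df$participant, df$outcome, sep = ".")
  out <- list()
  for (k in unique(keys)) {
    rows <- df[keys == k, ]
    rows <- rows[order(rows$session), ]
    out[[k]] <- tryCatch(
      assessment_series(rows$participant[1], rows$outcome[1],
                        rows$session, rows$phase, rows$value),
      error = function(e) {
        abort(sprintf("series %s (lines %d-%d): %s", k, min(rows$line),
                      max(rows$line), conditionMessage(e)),
              class = "scedrink_invalid_input")
      })
  }
  out
}

#' Write assessment series to CSV
#'
#' Inverse of [read_assessments()].
#'
#' @param series_list named list of [assessment_series()].
#' @param path output CSV path.
#' @export
write_assessments <- function(series_list, path) {
  rows <- lapply(series_list, function(s) {
    data.frame(participant = s$participant, outcome = s$outcome,
               phase = s$observations$phase,
               session = s$observations$session,
               value = s$observations$value)
  })
  df <- do.call(rbind, rows)[, ASSESSMENT_COLUMNS]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a marker trajectory to a tab-separated export
#'
#' Plain-text TSV mirroring a motion-capture export: metadata lines
#' (sampling rate, axes, identifiers, marker names) followed by a `DATA`
#' line and one row per frame with `<marker>_X/_Y/_Z` columns in mm.
#'
#' @param traj a [marker_trajectory()].
#' @param path output file path.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "marker_trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "SCEDRINK_TRAJECTORY\t1",
    sprintf("SAMPLING_RATE_HZ\t%g", traj$sampling_rate),
    sprintf("FORWARD_AXIS\t%s", traj$forward_axis),
    sprintf("VERTICAL_AXIS\t%s", traj$vertical_axis),
    sprintf("PARTICIPANT\t%s", traj$participant_id),
    sprintf("TRIAL\t%s", traj$trial_id),
    paste(c("MARKERS", names(traj$markers)), collapse = "\t"),
    "DATA"), con)
  wide <- do.call(cbind, lapply(traj$markers, identity))
  colnames(wide) <- as.vector(vapply(names(traj$markers), function(nm)
    paste(nm, c("X", "Y", "Z"), sep = "_"), character(3)))
  utils::write.table(
    data.frame(frame = seq_len(nrow(wide)), wide, check.names = FALSE),
    con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

interpolate_gaps <- function(x, max_gap) {
  if (!anyNA(x)) return(list(x = x, n_gaps = 0L))
  runs <- logical_runs(is.na(x))
  gaps <- runs[runs$value, , drop = FALSE]
  too_long <- gaps$end - gaps$start + 1 > max_gap
  if (any(too_long)) {
    abort(sprintf("gap of %d frames exceeds the %d-frame interpolation limit",
                  max((gaps$end - gaps$start + 1)[too_long]), max_gap),
          class = "scedrink_invalid_input")
  }
  if (is.na(x[1]) || is.na(x[length(x)])) {
    abort("trajectory starts or ends with a gap; cannot interpolate",
          class = "scedrink_invalid_input")
  }
  idx <- which(!is.na(x))
  list(x = stats::approx(idx, x[idx], xout = seq_along(x))$y,
       n_gaps = nrow(gaps))
}

#' Read a marker trajectory from a tab-separated export
#'
#' Inverse of [write_trajectory()]. Short coordinate gaps (missing
#' values of at most `gap_max_frames` consecutive frames) are linearly
#' interpolated with a message; longer gaps are an error. The hand and
#' trunk markers are required.
#'
#' @param path TSV file path.
#' @param gap_max_frames longest interpolatable gap (default 10 frames).
#' @return a [marker_trajectory()].
#' @export
read_trajectory <- function(path, gap_max_frames = 10L) {
  lines <- readLines(path, n = 50)
  data_at <- which(lines == "DATA")[1]
  if (!startsWith(lines[1], "SCEDRINK_TRAJECTORY") || is.na(data_at)) {
    abort("unknown trajectory file dialect (missing header or DATA line)",
          class = "scedrink_invalid_input")
  }
  meta <- strsplit(lines[2:(data_at - 1)], "\t")
  meta <- stats::setNames(lapply(meta, `[`, -1), vapply(meta, `[`, "", 1))
  fs <- as.numeric(meta$SAMPLING_RATE_HZ[1])
  marker_names <- as.character(meta$MARKERS)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          skip = data_at, check.names = FALSE)
  if (any(diff(df$frame) != 1)) {
    abort("non-uniform frame numbering in trajectory file",
          class = "scedrink_invalid_input")
  }
  markers <- list()
  n_interp <- 0L
  for (nm in marker_names) {
    cols <- paste(nm, c("X", "Y", "Z"), sep = "_")
    if (!all(cols %in% names(df))) {
      abort(sprintf("marker '%s' declared but its columns are missing", nm),
            class = "scedrink_invalid_input")
    }
    m <- as.matrix(df[, cols])
    for (j in 1:3) {
      fixed <- interpolate_gaps(m[, j], gap_max_frames)
      m[, j] <- fixed$x
      n_interp <- n_interp + fixed$n_gaps
    }
    markers[[nm]] <- unname(m)
  }
  if (n_interp > 0) {
    message(sprintf("interpolated %d short gap(s) in %s", n_interp,
                    basename(path)))
  }
  marker_trajectory(markers, fs,
                    forward_axis = meta$FORWARD_AXIS[1] %||% "X",
                    vertical_axis = meta$VERTICAL_AXIS[1] %||% "Z",
                    participant_id = meta$PARTICIPANT[1] %||% NA_character_,
                    trial_id = meta$TRIAL[1] %||% NA_character_)
}

#' Bundled participant characteristics of the motivating study
#'
#' Characteristics and training dose of the six chronic-stroke
#' participants of the motivating single-case A-B-A study: age, sex, time
#' since stroke, baseline motor function (FMA-UE median), total and
#' per-session active training time, and repetition counts.
#'
#' @return tibble with one row per participant.
#' @export
participant_characteristics <- function() {
  path <- system.file("extdata", "table1_participants.csv",
                      package = "scedrink")
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Summarise training dose and chronicity across participants
#'
#' Means over participants of the total active training time, the average
#' active training time per session, and the time since stroke.
#'
#' @param characteristics tibble as returned by
#'   [participant_characteristics()].
#' @return one-row tibble: `n_participants`,
#'   `mean_total_training_min` (and its hour equivalent),
#'   `mean_training_per_session_min`, `mean_years_since_stroke`.
#' @export
training_time_summary <- function(characteristics = participant_characteristics()) {
  tibble::tibble(
    n_participants = nrow(characteristics),
    mean_total_training_min = mean(characteristics$total_training_min),
    mean_total_training_h = mean(characteristics$total_training_min) / 60,
    mean_training_per_session_min =
      mean(characteristics$training_per_session_min),
    mean_years_since_stroke = mean(characteristics$years_since_stroke))
}
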