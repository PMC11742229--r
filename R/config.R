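#' Study configuration
#'
#' Bundles every tunable of the pipeline with defaults that reproduce the
#' standard analysis constants: the published MCID bands per outcome, the
#' Tau-U settings (variant, p-value method, permutation budget, seed), the
#' kinematic extraction settings (6 Hz zero-phase low-pass, 2%-of-peak
#' onset fraction, 20 mm/s movement-unit amplitude limit, 150 ms peak
#' separation, 20 mm return tolerance, declared forward/vertical axes) and
#' the per-session trial aggregation statistic.
#'
#' @param ... named overrides of the top-level blocks `mcid`, `tauu`,
#'   `kinematics`, `aggregation`; partial lists are merged recursively
#'   into the defaults.
#' @return object of class `study_config` (a nested list).
#' @export
study_config <- function(...) {
  defaults <- list(
    mcid = default_mcid_bands(),
    tauu = list(variant = "AvB-trendA", p_method = "permutation",
                n_permutations = 10000L, exact_limit = 50000L,
                seed = 20260101L),
    kinematics = list(filter_cutoff = 6, onset_fraction = 0.02,
                      amplitude_limit = 20, min_peak_separation = 150,
                      sustain_ms = 50, return_tolerance = 20,
                      min_bout_ms = 100, gap_max_frames = 10L,
                      forward_axis = "X", vertical_axis = "Z"),
    aggregation = "mean")
  overrides <- list(...)
  cfg <- modify_list_deep(defaults, overrides)
  validate_config(cfg)
  structure(cfg, class = "study_config")
}

modify_list_deep <- function(base, new) {
  for (nm in names(new)) {
    if (is.list(base[[nm]]) && is.list(new[[nm]]) &&
        !inherits(base[[nm]], "mcid_band")) {
      base[[nm]] <- modify_list_deep(base[[nm]], new[[nm]])
    } else {
      base[[nm]] <- new[[nm]]
    }
  }
  base
}

validate_config <- function(cfg) {
  k <- cfg$kinematics
  for (f in c("filter_cutoff", "onset_fraction", "amplitude_limit",
              "min_peak_separation", "sustain_ms", "return_tolerance",
              "min_bout_ms")) {
    if (!is.numeric(k[[f]]) || k[[f]] <= 0) {
      abort(sprintf("kinematics$%s must be positive", f),
            class = "scedrink_config_error")
    }
  }
  if (!cfg$aggregation %in% c("mean", "median")) {
    abort("aggregation must be 'mean' or 'median'",
          class = "scedrink_config_error")
  }
  if (!cfg$tauu$p_method %in% c("permutation", "normal_approx")) {
    abort("tauu$p_method must be 'permutation' or 'normal_approx'",
          class = "scedrink_config_error")
  }
  invisible(cfg)
}

#' Read a study configuration from a YAML file
#'
#' The file may override any subset of the defaults; the `mcid:` block
#' maps outcome names to `lower`/`upper`/`units`/`improvement_direction`
#' fields, the other blocks mirror [study_config()].
#'
#' @param path YAML file path.
#' @return a [study_config()].
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$mcid)) {
    raw$mcid <- lapply(stats::setNames(names(raw$mcid), names(raw$mcid)),
                       function(oc) {
                         b <- raw$mcid[[oc]]
                         mcid_band(oc, b$lower,
                                   b$upper %||% b$lower, b$units %||% "",
                                   b$improvement_direction %||% 1)
                       })
  }
  do.call(study_config, raw)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
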