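#' @importFrom stats median pnorm quantile rnorm
#' @importFrom rlang abort warn .data
#' @importFrom utils combn head tail
NULL

KNOWN_OUTCOMES <- c("fma_ue", "arat", "grip_strength",
                    "movement_time", "movement_units", "trunk_displacement")
PHASE_LEVELS <- c("A1", "B", "A2", "FU")

#' Construct and validate an A-B-A assessment series
#'
#' One participant x outcome ordered series of repeated assessments across
#' the phases of a single-case experimental design: baseline (A1),
#' intervention (B), post-intervention (A2) and optional follow-up (FU).
#'
#' Validation enforces the instrument ranges (Fugl-Meyer upper-extremity
#' scores are integers in 0--66, ARAT scores integers in 0--57, kinematic
#' and grip values non-negative), strictly increasing session ordinals and
#' non-decreasing phase order A1 <= B <= A2 <= FU.
#'
#' @param participant participant identifier (scalar).
#' @param outcome outcome name; one of `fma_ue`, `arat`, `grip_strength`,
#'   `movement_time`, `movement_units`, `trunk_displacement`.
#' @param session integer vector of session ordinals, strictly increasing.
#' @param phase character vector of phase labels (`A1`, `B`, `A2`, `FU`).
#' @param value numeric vector of scores/measurements.
#' @return An object of class `assessment_series`: a list with
#'   `participant`, `outcome` and an `observations` tibble
#'   (`session`, `phase`, `value`).
#' @export
#' @examples
#' assessment_series("P1", "fma_ue",
#'                   session = 1:12,
#'                   phase = rep(c("A1", "B", "A2"), c(5, 2, 5)),
#'                   value = c(15, 15, 14, 15, 15, 16, 18, 19, 20, 20, 21, 20))
assessment_series <- function(participant, outcome, session, phase, value) {
  outcome <- match.arg(outcome, KNOWN_OUTCOMES)
  n <- length(session)
  if (length(phase) != n || length(value) != n) {
    abort("`session`, `phase` and `value` must have equal length",
          class = "scedrink_invalid_input")
  }
  if (n == 0) {
    abort("an assessment series needs at least one observation",
          class = "scedrink_invalid_input")
  }
  if (!all(phase %in% PHASE_LEVELS)) {
    abort(paste0("unknown phase label(s): ",
                 paste(setdiff(unique(phase), PHASE_LEVELS), collapse = ", ")),
          class = "scedrink_invalid_input")
  }
  session <- as.integer(session)
  if (any(session <= 0) || any(diff(session) <= 0)) {
    abort("session ordinals must be positive and strictly increasing",
          class = "scedrink_invalid_input")
  }
  ord <- match(phase, PHASE_LEVELS)
  if (any(diff(ord) < 0)) {
    abort("phases must appear in non-decreasing order A1, B, A2, FU",
          class = "scedrink_invalid_input")
  }
  check_outcome_range(outcome, value, participant)
  structure(
    list(participant = as.character(participant), outcome = outcome,
         observations = tibble::tibble(session = session, phase = phase,
                                       value = as.numeric(value))),
    class = "assessment_series")
}

check_outcome_range <- function(outcome, value, participant = "?") {
  bad <- switch(outcome,
    fma_ue = value < 0 | value > 66 | value != round(value),
    arat   = value < 0 | value > 57 | value != round(value),
    value < 0)
  if (any(bad, na.rm = TRUE)) {
    ceiling_txt <- switch(outcome, fma_ue = " (integer, ceiling 66)",
                          arat = " (integer, ceiling 57)", " (non-negative)")
    abort(sprintf("participant %s: %s value(s) out of range%s: %s",
                  participant, outcome, ceiling_txt,
                  paste(value[bad], collapse = ", ")),
          class = "scedrink_invalid_input")
  }
  invisible(TRUE)
}

#' @export
print.assessment_series <- function(x, ...) {
  cat(sprintf("<assessment_series> %s / %s: %d sessions (%s)\n",
              x$participant, x$outcome, nrow(x$observations),
              paste(sprintf("%s n=%d", names(table(x$observations$phase)),
                            as.integer(table(x$observations$phase))),
                    collapse = ", ")))
  invisible(x)
}

#' Extract the values of one phase from an assessment series
#'
#' @param series an [assessment_series()].
#' @param phase phase label (`A1`, `B`, `A2` or `FU`).
#' @return numeric vector of the phase's values in session order.
#' @export
phase_values <- function(series, phase) {
  stopifnot(inherits(series, "assessment_series"))
  phase <- match.arg(phase, PHASE_LEVELS)
  series$observations$value[series$observations$phase == phase]
}

#' Kendall S statistic of a single ordered series
#'
#' The signed pair count `sum_{i<j} sign(x_j - x_i)`; tied pairs contribute
#' zero. Positive values indicate an increasing trend. This is the building
#' block of the within-phase trend terms of Tau-U.
#'
#' @param values numeric vector, length >= 2, in temporal order.
#' @return integer S statistic in `[-n(n-1)/2, n(n-1)/2]`.
#' @export
#' @examples
#' kendall_s(c(1, 2, 3))    #  3
#' kendall_s(c(5, 5, 5))    #  0
#' kendall_s(c(2, 1, 3, 0)) # -2
kendall_s <- function(values) {
  if (!is.numeric(values) || length(values) < 2) {
    abort("kendall_s() needs at least 2 numeric values",
          class = "scedrink_invalid_input")
  }
  d <- sign(outer(values, values, "-"))
  as.integer(sum(d[lower.tri(d)]))
}

#' Signed nonoverlap pair count between two phases
#'
#' Counts, over all cross-phase pairs, how many post-phase values exceed a
#' pre-phase value minus how many fall below one:
#' `#\{(i,j): b_j > a_i\} - #\{(i,j): b_j < a_i\}`. Ties contribute zero.
#' Divided by `n_a * n_b` this is the uncorrected nonoverlap Tau (an
#' affine transform of the Mann-Whitney U statistic).
#'
#' @param a numeric vector of the first (baseline) phase, non-empty.
#' @param b numeric vector of the second (post) phase, non-empty.
#' @return integer S in `[-n_a n_b, n_a n_b]`.
#' @export
#' @examples
#' pairwise_s_between(c(1, 1), c(2, 2)) # 4: complete nonoverlap
#' pairwise_s_between(c(1, 2), c(1, 2)) # 0
pairwise_s_between <- function(a, b) {
  if (length(a) < 1 || length(b) < 1) {
    abort("both phases must be non-empty", class = "scedrink_invalid_input")
  }
  as.integer(sum(sign(outer(b, a, "-"))))
}

tau_u_numerator <- function(s_ab, s_trend_a, s_trend_b, variant) {
  switch(variant,
         "AvB"               = s_ab,
         "AvB-trendA"        = s_ab - s_trend_a,
         "AvB+trendB"        = s_ab + s_trend_b,
         "AvB+trendB-trendA" = s_ab + s_trend_b - s_trend_a,
         abort(sprintf("unknown Tau-U variant '%s'", variant),
               class = "scedrink_config_error"))
}

#' Baseline-trend-corrected Tau-U effect size
#'
#' Computes the Tau-U family of nonoverlap effect sizes between a baseline
#' phase and a comparison phase of a single-case design. The default
#' variant, `"AvB-trendA"`, subtracts the within-baseline Kendall-S trend
#' count from the between-phase nonoverlap count before normalising by
#' `n_a * n_b`, so that an apparent effect explained by a pre-existing
#' baseline trend is discounted:
#' \deqn{\tau_U = (S_{AB} - S_{trendA}) / (n_A n_B)}
#'
#' Because the trend count is bounded by `n_a (n_a - 1) / 2` rather than
#' `n_a * n_b`, the corrected index can exceed 1 in magnitude; such values
#' are reported unclamped with `exceeds_unit_range = TRUE`.
#'
#' @param a baseline-phase (A1) values in session order; length >= 2 for
#'   trend-correcting variants.
#' @param b comparison-phase (A2) values in session order, non-empty.
#' @param variant one of `"AvB-trendA"` (default), `"AvB"`,
#'   `"AvB+trendB"`, `"AvB+trendB-trendA"`.
#' @param p_method `"permutation"` (default; exact enumeration of all phase
#'   reassignments when feasible, otherwise seeded Monte-Carlo) or
#'   `"normal_approx"` (see [tau_p_value()]).
#' @param n_permutations Monte-Carlo draws when enumeration is infeasible.
#' @param exact_limit enumerate exactly when `choose(n_a + n_b, n_a)` does
#'   not exceed this.
#' @param seed integer seed for the Monte-Carlo fallback.
#' @return An object of class `tau_u_result` with fields `n_a`, `n_b`,
#'   `s_ab`, `s_trend_a`, `s_trend_b`, `tau_ab`, `tau_u`, `variant`,
#'   `p_value`, `p_method`, `effect_band`, `exceeds_unit_range`.
#' @export
#' @examples
#' tau_u(c(1, 2, 3), c(4, 5, 6))$tau_u          # (9 - 3) / 9 = 0.667
#' tau_u(rep(5, 5), rep(9, 5))$tau_u            # 1: full nonoverlap
#' tau_u(c(1, 2), c(1, 2))$tau_u                # (0 - 1) / 4 = -0.25
tau_u <- function(a, b, variant = "AvB-trendA",
                  p_method = c("permutation", "normal_approx"),
                  n_permutations = 10000L, exact_limit = 50000L,
                  seed = 20260101L) {
  p_method <- match.arg(p_method)
  if (length(b) < 1) {
    abort("comparison phase is empty", class = "scedrink_invalid_input")
  }
  trend_variants <- c("AvB-trendA", "AvB+trendB-trendA")
  if (variant %in% trend_variants && length(a) < 2) {
    abort(paste("baseline has fewer than 2 points; a baseline trend cannot",
                "be estimated - use variant = 'AvB' (uncorrected Tau)"),
          class = "scedrink_invalid_input")
  }
  if (length(a) < 1) {
    abort("baseline phase is empty", class = "scedrink_invalid_input")
  }
  n_a <- length(a); n_b <- length(b)
  s_ab <- pairwise_s_between(a, b)
  s_trend_a <- if (n_a >= 2) kendall_s(a) else 0L
  s_trend_b <- if (n_b >= 2) kendall_s(b) else 0L
  num <- tau_u_numerator(s_ab, s_trend_a, s_trend_b, variant)
  tu <- num / (n_a * n_b)
  res <- structure(
    list(n_a = n_a, n_b = n_b, s_ab = s_ab,
         s_trend_a = as.integer(s_trend_a), s_trend_b = as.integer(s_trend_b),
         tau_ab = s_ab / (n_a * n_b), tau_u = tu, variant = variant,
         p_value = NA_real_, p_method = p_method,
         effect_band = classify_effect_size(tu),
         exceeds_unit_range = abs(tu) > 1,
         a = as.numeric(a), b = as.numeric(b)),
    class = "tau_u_result")
  res$p_value <- tau_p_value(res, method = p_method,
                             n_permutations = n_permutations,
                             exact_limit = exact_limit, seed = seed)
  res
}

#' @export
print.tau_u_result <- function(x, ...) {
  cat(sprintf(
    "<tau_u_result> %s: tau_u = %.3f (%s), tau_AB = %.3f, p = %.4g [%s]\n",
    x$variant, x$tau_u, x$effect_band, x$tau_ab, x$p_value, x$p_method))
  if (x$exceeds_unit_range) {
    cat("  note: |tau_u| > 1 (trend correction exceeds the pair-count",
        "denominator); reported unclamped\n")
  }
  invisible(x)
}

# All C(n, n_a) assignments of pooled positions to the baseline phase,
# or a seeded Monte-Carlo sample of them. Columns are sorted position sets,
# preserving the pooled temporal order within each phase.
phase_assignments <- function(n, n_a, exact_limit, n_permutations, seed) {
  n_total <- choose(n, n_a)
  if (n_total <= exact_limit) {
    list(exact = TRUE, idx = combn(n, n_a))
  } else {
    idx <- withr_seed(seed, {
      vapply(seq_len(n_permutations),
             function(i) sort(sample.int(n, n_a)), integer(n_a))
    })
    list(exact = FALSE, idx = idx)
  }
}

# evaluate a scoped RNG seed without disturbing the caller's RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

tau_u_for_assignments <- function(v, idx, variant) {
  n <- length(v); n_a <- nrow(idx); n_b <- n - n_a
  d <- sign(outer(v, v, "-")) # d[j, i] = sign(v_j - v_i)
  apply(idx, 2, function(ai) {
    bi <- setdiff(seq_len(n), ai)
    s_ab <- sum(d[bi, ai])
    # trend counts: pairs within each phase, in pooled (temporal) order
    s_ta <- trend_count(d, ai)
    s_tb <- trend_count(d, bi)
    tau_u_numerator(s_ab, s_ta, s_tb, variant) / (n_a * n_b)
  })
}

trend_count <- function(d, pos) {
  k <- length(pos)
  if (k < 2) return(0)
  m <- d[pos, pos, drop = FALSE]
  sum(m[lower.tri(m)])
}

#' p-value for a Tau-U result
#'
#' Two p-value conventions are offered. The default, `"permutation"`, forms
#' the null distribution of the chosen Tau-U statistic under random
#' reassignment of the pooled `n_a + n_b` values to the two phases, keeping
#' the pooled temporal order within each phase so the trend terms remain
#' meaningful. All `choose(n_a + n_b, n_a)` assignments are enumerated when
#' their number does not exceed `exact_limit`; otherwise a seeded
#' Monte-Carlo sample is drawn and the observed statistic is included in
#' both numerator and denominator. The p-value is two-sided:
#' the proportion of assignments with `|tau_u*| >= |tau_u|`.
#'
#' `"normal_approx"` uses `z = S / sd(S)` for the combined numerator `S`,
#' with null variance the sum of the Mann-Whitney variance
#' `n_a n_b (n_a + n_b + 1) / 3` for the between-phase count and the
#' Kendall variance `n (n - 1)(2 n + 5) / 18` for each included trend
#' count. This convention is approximate (it ignores the covariance of the
#' components and any tie correction) and is labelled as such in output.
#'
#' @param result a `tau_u_result` from [tau_u()].
#' @param method `"permutation"` or `"normal_approx"`.
#' @inheritParams tau_u
#' @return p-value in `[0, 1]`.
#' @export
tau_p_value <- function(result, method = c("permutation", "normal_approx"),
                        n_permutations = 10000L, exact_limit = 50000L,
                        seed = 20260101L) {
  stopifnot(inherits(result, "tau_u_result"))
  if (length(method) == 1 && !method %in% c("permutation", "normal_approx")) {
    abort(sprintf("unknown p-value method '%s'", method),
          class = "scedrink_config_error")
  }
  method <- match.arg(method)
  if (method == "permutation") {
    if (n_permutations < 1000) {
      abort("n_permutations must be >= 1000", class = "scedrink_config_error")
    }
    v <- c(result$a, result$b)
    asg <- phase_assignments(length(v), result$n_a, exact_limit,
                             n_permutations, seed)
    taus <- tau_u_for_assignments(v, asg$idx, result$variant)
    obs <- abs(result$tau_u) - 1e-12
    if (asg$exact) {
      mean(abs(taus) >= obs)
    } else {
      (1 + sum(abs(taus) >= obs)) / (length(taus) + 1)
    }
  } else {
    n_a <- result$n_a; n_b <- result$n_b
    s <- tau_u_numerator(result$s_ab, result$s_trend_a, result$s_trend_b,
                         result$variant)
    v <- n_a * n_b * (n_a + n_b + 1) / 3
    if (result$variant %in% c("AvB-trendA", "AvB+trendB-trendA")) {
      v <- v + n_a * (n_a - 1) * (2 * n_a + 5) / 18
    }
    if (result$variant %in% c("AvB+trendB", "AvB+trendB-trendA")) {
      v <- v + n_b * (n_b - 1) * (2 * n_b + 5) / 18
    }
    if (s == 0) 1 else min(1, 2 * pnorm(-abs(s) / sqrt(v)))
  }
}

#' Classify a Tau-U value into the conventional effect-size bands
#'
#' Bands on the magnitude: 0.00--0.25 very low, 0.26--0.49 low, 0.50--0.69
#' moderate, 0.70--0.89 large, 0.90--1.00 very large. Trend-corrected
#' values above 1 in magnitude also classify as very large.
#'
#' @param tau_u finite numeric Tau-U value.
#' @return one of `"very_low"`, `"low"`, `"moderate"`, `"large"`,
#'   `"very_large"`.
#' @export
#' @examples
#' classify_effect_size(0.72) # "large"
#' classify_effect_size(0.68) # "moderate"
classify_effect_size <- function(tau_u) {
  if (!is.numeric(tau_u) || length(tau_u) != 1 || !is.finite(tau_u)) {
    abort("tau_u must be a single finite number",
          class = "scedrink_invalid_input")
  }
  t <- abs(tau_u)
  if (t <= 0.25) "very_low"
  else if (t <= 0.49) "low"
  else if (t <= 0.69) "moderate"
  else if (t <= 0.89) "large"
  else "very_large"
}

#' MCID threshold band for one outcome
#'
#' A minimal clinically important difference (MCID) band: the published
#' lower and upper thresholds for a clinically meaningful change on one
#' outcome, with the direction in which change counts as improvement.
#'
#' @param outcome outcome name.
#' @param lower minimum MCID threshold (> 0).
#' @param upper maximum MCID threshold (defaults to `lower` when a single
#'   value is published).
#' @param units unit string.
#' @param improvement_direction `+1` when higher scores are better
#'   (`fma_ue`, `arat`, `grip_strength`), `-1` when lower values are better
#'   (`movement_time`, `movement_units`, `trunk_displacement`).
#' @return An object of class `mcid_band`.
#' @export
mcid_band <- function(outcome, lower, upper = lower, units = "",
                      improvement_direction = 1) {
  outcome <- match.arg(outcome, KNOWN_OUTCOMES)
  if (!(lower > 0 && lower <= upper)) {
    abort("need 0 < lower <= upper", class = "scedrink_config_error")
  }
  if (!improvement_direction %in% c(-1, 1)) {
    abort("improvement_direction must be +1 or -1",
          class = "scedrink_config_error")
  }
  structure(list(outcome = outcome, lower = lower, upper = upper,
                 units = units, improvement_direction = improvement_direction),
            class = "mcid_band")
}

#' Default MCID bands used for change reporting
#'
#' Published MCID thresholds for chronic stroke: FMA-UE 4.25--7.25 points,
#' ARAT 6 points, grip strength 11.1--13.7 lbf (5.0--6.2 kg, dominant vs
#' non-dominant arm), drinking-task movement time 2.5--5 s, movement units
#' 3--7 units, trunk displacement 2--5 cm. Higher is better for the three
#' clinical scales; lower is better for the three kinematic measures.
#'
#' @return named list of [mcid_band()] objects, one per outcome.
#' @export
default_mcid_bands <- function() {
  list(
    fma_ue = mcid_band("fma_ue", 4.25, 7.25, "points", 1),
    arat = mcid_band("arat", 6, 6, "points", 1),
    grip_strength = mcid_band("grip_strength", 11.1, 13.7, "lbf", 1),
    movement_time = mcid_band("movement_time", 2.5, 5, "s", -1),
    movement_units = mcid_band("movement_units", 3, 7, "units", -1),
    trunk_displacement = mcid_band("trunk_displacement", 2, 5, "cm", -1))
}

#' MCID-referenced change between baseline and post-intervention
#'
#' Computes the difference in phase medians between baseline (A1) and
#' post-intervention (A2) and expresses it as a percentage of the lower
#' MCID threshold, signed by the improvement direction: 100 means the
#' change exactly reached the established MCID. Even-count medians are the
#' midpoint of the central pair.
#'
#' @param series an [assessment_series()] with at least one A1 and one A2
#'   observation.
#' @param band the [mcid_band()] for the series' outcome.
#' @return An object of class `change_report`: `median_a1`, `median_a2`,
#'   `delta` (A2 - A1), `percent_of_mcid`, `reached_lower_mcid`,
#'   `reached_upper_mcid`.
#' @export
mcid_change <- function(series, band) {
  stopifnot(inherits(series, "assessment_series"), inherits(band, "mcid_band"))
  if (!identical(series$outcome, band$outcome)) {
    abort(sprintf("MCID band is for '%s' but the series outcome is '%s'",
                  band$outcome, series$outcome),
          class = "scedrink_config_error")
  }
  a1 <- phase_values(series, "A1")
  a2 <- phase_values(series, "A2")
  for (ph in c(A1 = "A1", A2 = "A2")) {
    if (length(phase_values(series, ph)) == 0) {
      abort(sprintf("series %s/%s has no %s observations",
                    series$participant, series$outcome, ph),
            class = "scedrink_invalid_input")
    }
  }
  m1 <- median(a1); m2 <- median(a2)
  delta <- m2 - m1
  improvement <- delta * band$improvement_direction
  structure(
    list(median_a1 = m1, median_a2 = m2, delta = delta,
         percent_of_mcid = 100 * improvement / band$lower,
         reached_lower_mcid = improvement >= band$lower,
         reached_upper_mcid = improvement >= band$upper),
    class = "change_report")
}

#' @export
print.change_report <- function(x, ...) {
  cat(sprintf(
    "<change_report> medians A1 %.2f -> A2 %.2f (delta %+.2f): %.1f%% of MCID%s\n",
    x$median_a1, x$median_a2, x$delta, x$percent_of_mcid,
    if (x$reached_upper_mcid) ", beyond upper threshold"
    else if (x$reached_lower_mcid) ", reached" else ""))
  invisible(x)
}

#' Numeric substrate for visual analysis of one phase
#'
#' Summaries used in structured visual analysis of single-case data:
#' level (median), range as a variability measure, and the sign of the
#' Kendall-S trend. The consensus visual judgment itself is a human task
#' and is not modelled.
#'
#' @param series an [assessment_series()].
#' @param phase phase label present in the series.
#' @return one-row tibble: `phase`, `n`, `median`, `min`, `max`, `range`,
#'   `trend_sign` (-1/0/+1), `trend_defined` (FALSE for single-point
#'   phases, where the sign is reported as 0).
#' @export
phase_descriptives <- function(series, phase) {
  v <- phase_values(series, phase)
  if (length(v) == 0) {
    abort(sprintf("phase %s absent from series %s/%s", phase,
                  series$participant, series$outcome),
          class = "scedrink_invalid_input")
  }
  trend_defined <- length(v) >= 2
  tibble::tibble(
    phase = phase, n = length(v), median = median(v),
    min = min(v), max = max(v), range = max(v) - min(v),
    trend_sign = if (trend_defined) sign(kendall_s(v)) else 0L,
    trend_defined = trend_defined)
}
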