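---
title: "Methods: single-case Tau-U statistics and drinking-task kinematics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-case Tau-U statistics and drinking-task kinematics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scedrink)
```

## The analysis model

`scedrink` analyses A-B-A single-case experimental designs in upper-limb
stroke rehabilitation: each participant is assessed repeatedly through a
baseline phase (A1), an intervention phase (B), a post-intervention
phase (A2) and optionally a follow-up (FU). Because such series are
short (typically 5 sessions per measurement phase), ordinal or coarsely
discrete (integer clinical scores), and autocorrelated in unknown ways,
the package uses rank-based nonoverlap statistics rather than parametric
models.

### Tau-U

For baseline values $a_1,\dots,a_{n_A}$ and post-intervention values
$b_1,\dots,b_{n_B}$, the signed nonoverlap count is

$$S_{AB} = \sum_{i,j} \operatorname{sign}(b_j - a_i),$$

an affine transform of the Mann–Whitney $U$ statistic, and the
within-baseline trend count is the Kendall S statistic

$$S_{trendA} = \sum_{i<j} \operatorname{sign}(a_j - a_i).$$

The default summary index subtracts the baseline trend before
normalising:

$$\tau_U = \frac{S_{AB} - S_{trendA}}{n_A\, n_B}.$$

Ties contribute zero to every count and no tie correction is applied to
the denominator — assessment scores are coarse integers, so ties are
common and must be handled deterministically. Three other family members
(`AvB`, `AvB+trendB`, `AvB+trendB-trendA`, all with denominator
$n_A n_B$) are available but not default.

Two properties of this definition matter in practice and are covered by
tests:

* Because $S_{trendA}$ is bounded by $n_A(n_A-1)/2$ while $S_{AB}$ is
  bounded by $n_A n_B$, $|\tau_U|$ can exceed 1 (up to
  $1 + (n_A-1)/(2 n_B)$). Such values are reported unclamped with an
  `exceeds_unit_range` flag — clamping would discard information — and
  classify as "very large".
* The baseline-trend correction is *partial* by construction: a genuine
  trend that continues through the intervention into a distant A2 phase
  saturates $S_{AB}$ at $n_A n_B$ while the subtracted trend count
  saturates at $n_A(n_A-1)/2$. With $n_A=n_B=5$ and a strong continuing
  drift, $\tau_U$ plateaus around $0.6$–$0.8$, not at 0. The package
  therefore reports the uncorrected $\tau_{AB}$ alongside $\tau_U$ so
  that the size of the correction is always visible.

### p-values

The study-grade calculators for these statistics do not document their
p-value convention, so the package makes its own convention explicit and
reproducible. The default is a **permutation test**: the null
distribution of the chosen $\tau_U$ statistic under random reassignment
of the pooled $n_A + n_B$ values to the two phases, preserving the
pooled temporal order within each phase so the trend term stays
meaningful. All $\binom{n_A+n_B}{n_A}$ assignments are enumerated
exactly whenever their number is at most `exact_limit` (default 50 000,
which covers every realistic single-case series; for $n_A=n_B=5$ there
are only 252); otherwise a seeded Monte-Carlo sample is drawn and the
observed statistic is included in numerator and denominator. The
p-value is two-sided on $|\tau_U|$. Exact enumeration makes the p-value
super-uniform under the null; the test suite verifies that the
rejection rate at $\alpha = 0.05$ over 2000 null replicates stays
inside the 99% binomial envelope.

A **normal approximation** is offered as a labelled alternative:
$z = S/\mathrm{sd}(S)$ for the combined numerator, with variance the sum
of the Mann–Whitney variance $n_A n_B (n_A+n_B+1)/3$ and the Kendall
variance $n(n-1)(2n+5)/18$ for each included trend term. It ignores the
covariance between components and any tie correction, and is recorded
as `normal_approx` in every result so the convention used is never
ambiguous.

### Effect bands and MCID reporting

Effect sizes are classified on $|\tau_U|$ into the conventional closed
bands very low (0.00–0.25), low (0.26–0.49), moderate (0.50–0.69),
large (0.70–0.89) and very large (0.90–1.00; values above 1 included).
Clinical interpretation uses the published MCID bands per outcome
(defaults in `default_mcid_bands()`): FMA-UE 4.25–7.25 points, ARAT 6
points, grip strength 11.1–13.7 lbf, drinking-task movement time
2.5–5 s, movement units 3–7, trunk displacement 2–5 cm; higher is
better for the clinical scales and lower for the kinematic measures.
The change score is the difference in phase medians (even-count medians
are midpoints of the central pair), expressed as a percentage of the
lower MCID threshold and signed by the improvement direction, so that
100% means the change just reached the established MCID.

The follow-up phase is excluded from all inferential statistics and
retained only in descriptives, and no multiple-testing correction is
applied (the report records the number of tests performed instead) —
both deliberate mirror-images of standard practice for this design.

## Kinematic extraction

All extraction operates on 3D marker positions in mm sampled uniformly
(study rate 240 Hz), with a **declared** forward (sagittal) and vertical
axis — no automatic axis inference, because the sign of trunk
compensation depends on it.

* **Filtering and differentiation.** Positions are low-pass filtered
  with a second-order Butterworth applied forward-backward (zero phase,
  so peak timings are not shifted) at a default cutoff of 6 Hz, the
  standard choice for reach kinematics: it passes the 2–5 Hz content of
  segmented submovements while suppressing marker jitter. Because
  `signal::filtfilt` assumes zero endpoint levels, the signal is
  extended by reflection at both ends before filtering and trimmed
  after; without this, a trajectory ending away from zero acquires a
  large spurious terminal velocity. Speed is the Euclidean norm of the
  central-difference derivative.
* **Onset and offset.** The trial starts when hand speed first exceeds
  2% of its peak and stays above it for at least 50 ms, and ends at the
  last sub-threshold crossing at which the hand is within 20 mm of its
  onset position ("back at the initial position"). A candidate run must
  additionally reach 10% of peak speed: at realistic noise levels, 2% of
  the peak of a slow impaired movement (~5 mm/s) is reachable by
  filtered marker noise for longer than 50 ms, and the movement-reach
  guard rejects such blips without moving either published threshold.
  If the hand never returns within tolerance, the offset falls back to
  the final sub-threshold crossing and the result is flagged.
* **Phase segmentation.** The five phases (reaching, forward transport,
  drinking, back transport, returning) are delimited with the cup
  marker, which is stationary except during the two transports. Bout
  cores are intervals where cup speed exceeds 20% of its peak for at
  least 100 ms — a level marker noise cannot reach — grouped into
  forward and back transport at the longest cup rest (the drinking
  pause), and extended outward to the 2% crossings. This mirrors the
  movement-time rule, recovers programmed boundaries within ±1 frame on
  noise-free trials, and is robust at 0.5 mm noise. The maximal cup
  elevation is checked to fall inside the detected drinking interval
  (a warning otherwise). Explicit boundary annotations may be supplied
  instead and are honoured verbatim after ordering validation.
* **Movement units.** Within each of the four transport phases,
  candidate units are local-minimum-to-next-local-maximum speed
  excursions with amplitude above 20 mm/s; accepted peaks must be at
  least 150 ms apart, and when two conflict the larger-amplitude peak
  is kept (a deterministic tie-break). The window start acts as an
  implicit trough so a phase's principal bell always counts. The
  drinking pause contributes nothing. Raising either threshold can only
  reduce the count (tested as a monotonicity property). Phases shorter
  than 2 frames count 0 with a warning.
* **Trunk displacement** is the maximum of the trunk marker's
  forward-axis coordinate over the trial minus its value at onset,
  floored at zero (backward lean does not count as compensation) and
  reported in cm.
* **Aggregation.** Sessions collect several trials; both mean and
  median of every metric are reported and the configured statistic
  (default mean) feeds the assessment series for the Tau-U layer.

## The synthetic-data generator

`generate_trial()` composes hand, cup and trunk paths from quintic
minimum-jerk segments — the standard model of smooth point-to-point
reaching, with bell-shaped speed peaking at $1.875\,A/T$ — through the
task geometry (cup 300 mm from the start, lifted 200 mm to the mouth,
default phase durations 1.5/1.2/2/1.2/1.5 s at a comfortable self-paced
speed, 0.5 s stationary padding). Submovements are injected as
minimum-jerk speed bumps along the path, with the main segment
amplitude rescaled so endpoints are preserved; isotropic Gaussian noise
(default sd 0.2 mm, typical optical-capture jitter) is added per
coordinate and frame under an explicit seed. The same bell family is
used for main segments and injections so that injected peaks are
filter-stable.

Ground truth is computed from the *noiseless analytic* profiles on the
sample grid, independent of the extraction pipeline: the 2%-crossing
onset/offset and movement time, the cup-bout boundaries, the programmed
trunk excursion, and the movement-unit count obtained by applying the
20 mm/s / 150 ms excursion rule directly to the analytic speed (no
filtering or numerical differentiation). The parametric view — "4 plus
every injection with amplitude > 20 mm/s and peaks ≥ 150 ms apart" — is
reported as per-injection qualifying flags, but the analytic-rule count
is authoritative: an injection's *expressed* excursion depends on the
local slope of the main profile (a bump riding a steep fall may express
far less than its nominal amplitude), so only well-placed injections
(sharp relative to the local slope, e.g. on the slow transports of an
impaired-style trial) add exactly one unit each. The tests exercise
both regimes.

`generate_series()` draws A-B-A score series from a linear model —
baseline level and per-session trend, an intervention level shift
active in B and A2, an extra within-B trend, Gaussian noise — rounded
to the instrument grid (integers for FMA-UE/ARAT, 0.1 for kinematic
outcomes) and clipped to the instrument range. `simulate_study()`
assembles a whole multi-participant, six-outcome study, optionally
withholding kinematic outcomes from some participants to mimic patients
unable to complete the drinking task.

What the generator does **not** emulate: session-to-session
autocorrelation beyond a deterministic trend, marker occlusion and soft
tissue artefact (gaps are only synthesised in I/O tests), ceiling
effects mid-recovery, the biomechanics of grasp, or realistic
inter-trial variability structure. Passing tests therefore demonstrate
correctness of the *statistics and extraction rules* under controlled
conditions, not clinical validity on real recordings.

## Numerical choices and degenerate inputs

* Medians of even-count phases: midpoint of the central pair.
* `kendall_s` needs ≥ 2 values; trend-correcting Tau-U variants need
  $n_A \ge 2$ and direct the user to the uncorrected variant otherwise;
  single-point phases report trend sign 0 with a `trend_defined` flag.
* All-tie series give $\tau_U = 0$ with permutation p = 1.
* Trajectory gaps of ≤ 10 frames are linearly interpolated and logged;
  longer gaps are an error rather than silently bridged.
* Every stochastic routine (Monte-Carlo p-values, noise, simulated
  studies) takes an explicit integer seed; seeded runs are
  bit-reproducible and seeds are recorded in output metadata.

## Problem sizes used in the test suite

Statistical properties use series of 5+5 sessions (the design's
standard phase length): 2000 null replicates for calibration, 500 for
shift recovery, exact enumeration of all 252 phase reassignments per
replicate. Kinematic properties use single trials of ~8 s at 240 Hz
(~2000 frames), with 200 seeded replicates at the 0.5 mm noise stress
level. These sizes keep the full suite under a minute while leaving the
Monte-Carlo error well below every asserted margin.

## Known limitations

* The permutation test conditions on the observed values and preserves
  within-phase order only; it does not model serial dependence, so
  p-values under strong autocorrelation are approximate (a limitation
  shared by the statistic itself).
* The normal-approximation p-value ignores component covariance and tie
  corrections; it is provided for comparability, labelled, and never
  the default.
* Phase segmentation requires a cup marker or explicit annotations;
  tasks with a different object layout need the annotation path.
* MCID defaults are population-level values for chronic stroke and
  should be overridden (YAML `mcid:` block) for other populations.
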