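---
title: "Methods: complex-spike multiplexing analysis and its synthetic testbed"
author: "csmux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: complex-spike multiplexing analysis and its synthetic testbed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csmux)
```

## The scientific problem

Cerebellar Purkinje cells fire two kinds of action potentials. Complex spikes
(CSs) are rare (~1/s) events driven by the cell's single climbing fiber, and
their functional role is contested: error reporting, kinematic encoding,
timing, prediction. In a repetitive horizontal saccade task — a centrifugal
(CF) saccade to a 15-degree target, an occasional small corrective saccade,
and a centripetal (CP) return saccade — CS activity multiplexes several
streams: a direction- and amplitude-dependent burst just after each saccade, a
tonic component tracking the signed retinal error later in the postsaccadic
period, a burst after corrective saccades, a sharp component ~200 ms after
trial onset, perisaccadic suppression, and systematic changes in CS *duration*
(spikelet count) that are yoked to the rate changes.

`csmux` implements the analysis chain for such recordings — saccade detection,
event-locked kernel rate estimation, preferred-direction assignment, tuning
curves, bootstrap peak/trough timing, error-vs-kinematics disentangling,
CS-duration analysis, and per-cell encoding matrices — together with a
session simulator whose ground truth makes every estimator testable. Real
population results from such experiments depend on the recorded cells; this
package's claims are therefore *property* claims (parameter recovery, oracle
equivalence, calibration), checked by the test suite and
`scripts/acceptance.R`.

## The synthetic session generator

`session_config()` + `generate_behavior()` emulate the task structure: a
fixation period of 400–600 ms from trial onset, a target jump to ±15 deg, a CF
saccade after a ~170 ms latency, a corrective saccade when the retinal error
exceeds a trigger threshold (default 0.5 deg), target offset 700–900 ms after
the jump, a 100 ms intertrial gap, and a CP return saccade ~110 ms after the
fixation dot reappears. Eye positions are state-consistent: each CF saccade
launches from wherever the previous return saccade left the eye, so the trace
carries no artificial position drift.

Design choices the task description leaves open:

* **Velocity profile.** Saccades are minimum-jerk, because the closed form
  `v_peak = 1.875 * A / D` gives an analytic oracle for detector tests.
* **Fatigue.** A peak-velocity multiplier decays geometrically from 1 on the
  first trial to `fatigue_velocity_ratio` on the last; duration scales
  inversely so amplitude is preserved — the phenomenon of saccadic fatigue
  reduced to its two observable signatures.
* **Endpoint scatter.** Primary endpoints are `target + N(0, sd)` (default
  0.6 deg, matching a ±2 deg acceptance window); corrective saccades land with
  their own scatter (default 0.15 deg) rather than exactly on target, because a
  deterministic landing point produces degenerate amplitude distributions.
* **Measurement noise.** White position noise, default 0.02 deg — the scale of
  scleral search coils, the measurement standard for this preparation. At
  0.1 deg the low-pass-filtered velocity noise (~11 deg/s SD) sits above the
  10 deg/s corrective-saccade criterion; corrective detection therefore
  requires coil-grade noise, while primary detection is robust up to 0.1 deg.

`neuron_tuning()` + `generate_spikes()` define the latent CS rate as a sum of
interpretable components (baseline, suppression of the baseline in a window of
−75 to +85 ms around primary-saccade onset, offset-locked Gaussian bursts with
direction gain plus an amplitude slope, a tonic signed-error term 50–250 ms
after the saccade, corrective bursts, and a trial-onset bump whose size falls
off linearly with the lateness of the return saccade's arrival). Spikes are
drawn by Poisson thinning; behavior, CS, and SS streams are independently
seeded. Simple spikes are homogeneous Poisson with an enforced 10–20 ms pause
after every CS, the standard identity check for a CS/SS pair from one cell.

CS durations use a two-class model: a short mode (4.2 ms) and a long mode one
spikelet later (+1.8 ms). The long-class probability is
`clip01(spikelet_base_prob + spikelet_prob_gain * (2 * plogis(lambda - baseline) - 1))`,
so duration rides up and down with the rate excursion. The explicit base
probability (default 0.3) makes the baseline duration distribution bimodal;
setting both base and gain to zero yields all-short CSs, the degenerate case
some tests use.

## Analysis methods

**Saccade detection.** Velocity is the central difference of the position
trace after a zero-phase 2nd-order Butterworth low-pass (default 80 Hz, with
reflection padding so constant traces produce zero velocity). Primary saccades
are maximal runs of |v| ≥ 30 deg/s (runs separated by <10 ms merged), kept if
the horizontal amplitude is 13–17 deg; corrective saccades use 10 deg/s,
duration >10 ms, amplitude 0.2–2 deg, and must lie between a primary offset
and the next primary onset. Onset/offset are the first/last suprathreshold
samples. Events clipped by the trace boundary are discarded. The signed
retinal error is `active target - endpoint`, rightward positive.

**Rates.** Each CS is convolved with a normalized 5 ms SD Gaussian kernel
(truncated at ±5 SD and renormalized to exact unit mass); profiles are means
across events on a 1-ms grid. All analysis windows are half-open `[start,
end)` in ms: early postsaccadic `[0,100)` and late postsaccadic `[50,250)`
from primary offset, precorrective `[-200,0)` from corrective onset,
postcorrective `[0,100)` from corrective offset, trial-onset `[150,250)`, and
regression windows `[40,80)` / `[100,250)` from primary offset
(`analysis_windows()`).

**Preferred directions.** Primary PD uses the *probability* of CS firing in
the early postsaccadic window; corrective and error PDs use the *mean rate* in
their windows — the statistics differ deliberately, following the original
analysis wording. Exact ties resolve to +1 with a flag.

**Tuning curves.** `binned_tuning()` bins a covariate (0.5-deg amplitude bins
over 13–16 deg, 5-ms duration bins, 0.5-deg signed-error bins, ...), drops
bins with fewer than 10 events, computes a window statistic per bin, and fits
an OLS line through bin centers. Note that the *peak* of a noisy profile is
upward-biased by an amount that falls with the event count; bins with very
unequal counts can mask a slope in `peak_rate`, which is why the validation
uses `mean_rate` where the analytic expectation is available.

**Peak and trough timing.** `bootstrap_peak_time()` samples 50 cells with
replacement (cells need ≥10 trials per 5-ms duration bin), averages their
kernel rates, takes the argmax, and reports the mean and 2.5/97.5 percentiles
over 1000 replicates. `estimate_trough()` fits a quadratic to the baseline
(−200–0 ms from saccade onset) and a line to the 45 ms leading up to the peak,
and intersects the two continuous fits (quadratic roots, not grid samples);
the earliest intersection between baseline end and peak is the modulation
onset. The 45-ms span is anchored at the peak; the method is exact on
noiseless piecewise profiles but inherently sensitive to baseline noise when
the rise is shallow — the validation uses a steep constructed rise and reports
the mean error and CI coverage over seeded runs.

**Disentangling error from kinematics.** Because the error is defined from
the endpoint, amplitude and error are deterministically coupled *within* one
saccade class (A = 15 − E for rightward CF), and only pooling classes breaks
the coupling. Three tools mirror that logic: `pool_comparable_errors()`
(groups by signed-error bin, reports a Kruskal–Wallis amplitude-balance test),
`pool_mixed_errors()` (per amplitude bin, subsamples equal counts of positive
and negative errors — mean error *sign* is zero by construction),
`per_pc_multiple_regression()` (per-cell OLS of window CS counts on amplitude
and signed error). A caveat found while validating: with idealized
minimum-jerk kinematics the per-error-bin amplitude *distributions* are
bimodal mirror images; their means balance exactly, but a rank test of
distributional identity (Kruskal–Wallis) detects the shape difference in a
sizable fraction of simulated sessions. The package reports the KW statistic
as the original analysis did, and the tests assert the mean balance, which is
the property the pooling actually needs. Real recordings, with their richer
behavioral variability, are less degenerate than the simulator here.

**CS duration.** `percent_change_series()` computes a running average (50-ms
bins stepped at 10 ms) of CS duration, as percent change from the cell's mean
duration. `detect_epochs()` thresholds the population profile at the baseline
(−200 to −100 ms) mean ± 3 SD. When the profile carries an across-cell SEM,
the threshold SD is the baseline-pooled SEM — the sampling SD of the
population mean, which is well estimated — rather than the SD over the ~2
effectively independent baseline bins, whose estimation error otherwise makes
the 3-SD rule fire on noise. An epoch must outlast one bin width plus one step
(60 ms): every CS influences all sliding bins that cover it, so shorter
crossings can be produced by a single chance cluster.

**Encoding matrices.** For each cell and task parameter, events are split at
the parameter's median (ties to the lower group), rates compared with a
one-tailed Wilcoxon signed-rank test (upper group hypothesized higher);
direction tests compare the two directions with the preferred direction
hypothesized higher — note the circularity when the PD was chosen from the
same data, which is why calibration tests fix the hypothesized direction a
priori. Cells with fewer than 10 CSs in the window are `not_compared`.
The pairing convention (groups truncated to equal size, paired in event
order) is a declared choice isolated in one function; a paired test on
median-split groups is not otherwise fully specified. Binary
significance matrices are cross-correlated column-wise (Pearson, pairwise
complete); α = 0.05 with no multiplicity correction, matching the original
analysis — a correction can be applied downstream to the reported p-values.

## Numerical and validation notes

* Problem sizes in the tests (hundreds of trials, tens to hundreds of cells,
  50–200 bootstrap replicates) were chosen so each property is decided with
  comfortable statistical margin while the full suite runs in minutes.
* The trough validation draws trains from a constructed piecewise rate
  (flat baseline 2 spikes/s, linear rise of 0.6 spikes/s/ms from a known
  breakpoint) — an estimator-validation profile, deliberately steeper and
  stronger than a single cell's CS rate so the intersection is
  well-conditioned; the behavioral generator's latent trough has no closed
  form.
* Passing tests demonstrate correct *estimator* behavior under the generative
  model; they cannot certify features the simulator does not emulate —
  vertical saccade components, blink artifacts, drifting baselines,
  cell-to-cell latency heterogeneity, or non-Poisson CS statistics.
* All randomness is seeded; reruns are byte-identical. Bootstrap outputs are
  deterministic given their `seed` argument.

## What the pipeline writes

`run_pipeline()` executes detection, PD assignment, amplitude tuning,
encoding tests, and duration profiles per session, then population summaries
(fatigue table, encoding matrix, parameter cross-correlations, duration
epochs), all as CSV plus a JSON provenance record (package version, seeds,
config hash, per-stage event counts). `write_session()` / `read_session()`
define the on-disk session bundle (CSV + JSON); ground truth is written
alongside but never read by analysis code.
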