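---
title: "Detecting and quantifying TAN pause responses in timing tasks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and quantifying TAN pause responses in timing tasks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tanlab)
```

Striatal tonically active neurons (TANs) fire regularly at roughly 5–6
spikes/s and signal motivationally salient events with a brief depression of
that tonic firing — the *pause* — sometimes followed by a rebound excitation.
This vignette documents the models, conventions and numerical choices behind
`tanlab`'s pipeline for characterizing those pauses in interval-timing
behavior: what each stage assumes, which parameters matter, what the
synthetic generator does and does not emulate, and where the design was
genuinely open.

## Session model

A session binds one task configuration, a chronological trial-event table, a
unit table and a long-format spike table. Two conventions carry through
every stage:

* **Single clock.** All event and spike times are absolute seconds from
  session start. Alignment to events is always computed on demand and never
  stored, so there is one source of truth for time.
* **Half-open millisecond windows.** Analysis windows are expressed in ms
  relative to an alignment event and are half-open `[start, end)`: a spike
  exactly at the window end belongs to the next window, so adjacent windows
  tile without double counting.

Missing events (no bar release, no reward) are empty CSV cells and `NA` in
memory — never 0 or −1, since 0 is a legal time. Saved sessions are
byte-stable: fixed column order, 6 decimal places for seconds (1 µs, below
any physiologically meaningful resolution), so `save → load → save` is the
identity at the byte level.

## The behavioral task and its simulator

In the time-estimation task (TET) the cue's location instructs the minimum
waiting period `T` (`short_threshold`/`long_threshold`; presets 1.3/2.3 s
and 1.0/2.0 s). A trial is *correct* when the bar is released in
`[T, T + limited_hold]` (limited hold 2 s) and the target is contacted
within `movement_time_limit` (1 s); earlier releases are *underestimation*
errors, later ones *late release*; trials without a release or contact are
*excluded*. A release exactly at the threshold counts as correct — the
waiting period has elapsed — which fixes the one boundary the task rules
leave open. Error trials re-queue the same cue side immediately; otherwise
sides are pseudorandom, balanced within blocks of ten. In the Pavlovian
variant (PCT) reward simply arrives at `cue + T` with no action required.

The generator draws movement onset times (MOTs) per interval from a normal
distribution truncated at zero with `sd = weber_fraction × mean`, which is
the *scalar property* of interval timing in its simplest form. It does not
model the threshold-hugging skew that individual subjects can show on short
intervals, nor learning across sessions, eye or licking dynamics, or any
biophysics — so passing tests demonstrate correctness of the analysis chain
under scalar timing with stationary tonic firing, not robustness to every
idiosyncrasy of real data.

Preset calibration: no numeric MOT moments are published for this task, so
presets place the MOT mean at `threshold + 0.35 s`. The per-subject Weber
fractions (0.13 for the C presets, 0.20 for D) were chosen analytically so
that pooled correct rates land near the reported ~89% and ~82%: with
repeat-on-error scheduling the pooled correct rate is the *harmonic* mean of
the per-interval success probabilities (error trials multiply attempts at
the harder interval), i.e.

$$p_{pooled} = \frac{2}{1/p_{short} + 1/p_{long}}, \qquad
  p_{iv} = \Phi\!\left(\frac{0.35}{w\,(T_{iv}+0.35)}\right),$$

minus the small no-response probability (default 0.01).

## Spike trains

Baseline firing is a gamma-interval renewal process: inter-spike intervals
`Gamma(shape = k, rate = k λ)` with `λ = baseline_rate`. The shape `k`
(`firing_regularity`) defaults to 2 for TANs — tonically *regular* firing,
sub-Poisson variability — and 1 (Poisson) for PANs. No published ISI model
exists for these neurons, so regularity is an explicit parameter rather than
a fitted constant.

Event-locked responses multiply the rate by `rate_factor` inside
`[latency, latency + duration)` after their alignment event. Modulation is
applied by *thinning*: a baseline spike in an active window is kept with
probability `min(factor, 1)`, and where the combined factor exceeds 1 the
surplus rate is superposed as Poisson spikes. Thinning preserves the rate
ratio exactly in expectation, so an injected factor `f` is recovered as an
aligned-window rate of `f × baseline` — the property the magnitude stage is
tested against. Two optional couplings modulate the per-trial factor
linearly: on the trial's MOT (centered at the mean MOT of the affected
trials, so the mean depth stays at `rate_factor` while the magnitude-vs-MOT
slope equals the programmed slope) and on the trial's 1-based position
within a run of consecutive correct trials; pause factors are clipped to
[0, 1].

## Pause detection

The detector advances a `window_ms = 100` ms test window in `step_ms = 10`
ms increments over `scan_span_ms = [0, 1000)` ms after the alignment event.
Each step compares spike rates in the test window against the control
period — the 500 ms immediately before cue onset, for every alignment event —
with a Dunn-type rank z statistic (normal approximation, tie correction,
continuity correction), two-sided, at `alpha = 0.01` per step. A modulation
needs `min_run = 5` consecutive significant steps of the same sign; the
onset is the first step's start time (not its midpoint — the step start is
the convention chosen here), and the offset is the last significant step's
start plus one window width; offsets have no established definition in this
procedure, so this one is fixed as the package's convention. Increases are tracked symmetrically so rebounds can
be reported, but rebound quantification beyond flagging is out of scope.

Two numerical choices deserve emphasis:

* **Control subwindows.** A rank test between per-trial counts collected
  over a 500 ms window and counts collected over a 100 ms window is not
  exchangeable under the null: the two count distributions have different
  granularity (a 100 ms count at 6 Hz is 0 more than half the time), so the
  test statistic is biased and overdispersed, which manifests as spurious
  "decrease" detections. On null tonic trains this inflates the per-step
  significant-decrease rate to ~2.4% at nominal 0.5% and the unit-level
  false-pause rate to ~7%. The scan therefore tiles the control period into
  five 100 ms subwindows per trial and uses all of them as the control
  sample: both samples then share one null distribution, the step z is
  centered (mean ≈ 0, SD ≈ 1), and the empirical false-positive rate drops
  below 1% — the regime the ≥ 5-consecutive-steps rule was designed for.
* **Continuity correction.** The per-step and group rank tests subtract 0.5
  from |W − E[W]| before the normal approximation. This keeps the
  approximation within 0.02 of exact enumeration for group sizes of five
  and up (five per group is the smallest two-sided rank test that can reach
  the default `alpha = 0.01` at all); without it the worst-case error is
  about 0.05 even at 8 + 8. With heavy ties at very small samples the
  normal approximation is only good to about one decimal — the tests record
  this honestly — but detection operates on dozens of trials where the
  approximation is excellent.

The per-step `alpha` is deliberately *not* corrected for the ~91 sliding
steps: the run rule is the multiplicity control, and the false-positive
calibration on 200 null units verifies that the combination holds the
unit-level error below 5%. A `bonferroni` flag exists for sensitivity
analysis. Onset estimates are accurate to about one window width: a window
only partially overlapping a strong pause can already reach significance,
so onsets are biased early by up to `window_ms`, which is why recovery is
asserted within ±100 ms.

## Magnitude rating and population curves

Response magnitude is the signed percent change of the aligned rate from
baseline, `100 (r − b)/b`, rated for every unit in fixed quantification
windows — irrespective of individual responsiveness, so the population
statistics are not conditioned on detection. The shipped presets are the
per-subject windows established from detected pause onset/offset times
(cue: 93–309 ms for C on both intervals, 127–313 and 211–418 ms for D;
reward: 139–369 ms for C, 194–391 ms for D); `derive_quant_window()`
re-derives such windows from a set of detections by mean onset/offset or by
central coverage. The baseline is the same 500 ms pre-cue control period,
computed from the condition's own trials. Reward-aligned tables use
rewarded trials only (reward exists only there).

Population curves are unit-averaged PSTHs in non-overlapping 10 ms bins
with the SEM taken across units. Optional Gaussian smoothing is
parameterized directly as a kernel sigma in bins (default 25 when used for
region-comparison curves) with an edge-renormalized kernel; the smoothing
parameter sometimes quoted as a filter "alpha" has no recoverable
definition, so sigma is exposed as the configuration value instead.

## Unit classification

TAN/PAN labels come from baseline rate and spike width only: TAN if
`rate ≥ 3.5` spikes/s and width above the per-subject threshold (800 µs for
the C rule, 940 µs for D — midpoints between the reported class means,
which differ strongly between subjects); PAN if `rate ≤ 2.5` and width
below; everything between abstains as `unclassified`. The reported class
moments overlap these bands, so on populations drawn from them roughly 60%
of draws are decided while wrong labels stay under 10% — abstention is
deliberate, not failure. Task responsiveness, though usable as a supporting
criterion in practice, is excluded from the classifier to keep
classification independent of pause detection (no circularity). Spike
widths are standardized in microseconds throughout; source tables that mix
width units are interpreted as µs.

## Group statistics

* **Proportions**: uncorrected Pearson χ² on 2×2 tables (`chi2_2x2`,
  `prop_chi2`); no Yates correction, which is verified by reproducing five
  published χ² statistics from their printed counts to ±0.02. A `correct`
  flag enables Yates for sensitivity checks.
* **Magnitude contrasts**: `rank_compare` with `paired = TRUE` (signed-rank
  z) for within-neuron short-vs-long contrasts — within-neuron data are
  intrinsically paired — and `paired = FALSE` (rank-sum z) for
  between-region and between-subject contrasts. Published analyses name
  both tests for such contrasts; the flag makes the choice explicit.
* **MOT trends**: least-squares slope plus Spearman rho; per-trial
  magnitudes for these analyses are single-trial window rates against the
  condition baseline (`n = 1` per row) — noisier than any smoothed
  alternative but fully explicit. MOT binning tiles half-open 500 ms bins
  from zero.
* **Sequence trends**: runs of ≥ 5 consecutive correct trials are found on
  the pooled chronological trial sequence; within runs, per-trial
  magnitudes are averaged across units at each 1-based position and
  regressed on position. Opposite programmed couplings (cue pause
  deepening, reward pause weakening) are recovered with their signs.
* No multiple-testing correction is applied across this battery, matching
  standard practice for these analyses; each result reports its inputs
  (counts, n) for audit.

## Problem sizes and determinism

Every stochastic component takes an integer seed and is exactly
reproducible; a session preset regenerated with the same seed is identical
byte-for-byte after saving. The validation suite exercises the chain at the
sizes the procedures are meant for: 200 null units × 60 trials for
false-positive calibration, 50 units for pause recovery, 300 trials for
magnitude recovery, 10,000 trials per interval for the scalar property, 20
seeds for sequence-coupling recovery, and exhaustive enumeration (435 rank
configurations) for the rank-test oracle.

## Known limitations

* The generator's stationarity (constant baseline, fixed response
  parameters) cannot probe drift, bursting or slow motivational states.
* Onset/offset estimates inherit one-window-width smearing; they are not
  change-point estimates.
* Per-trial magnitudes are raw single-trial rates; low baselines make them
  coarse (a 200 ms window at 6 Hz holds ~1.2 spikes).
* Region labels enter only as per-unit metadata; no anatomical modeling.
* The classifier abstains on the overlap band by design; downstream
  analyses should treat `unclassified` as missing, not as PAN.
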