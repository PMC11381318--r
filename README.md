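# tanlab

Analysis of striatal **tonically active neurons** (TANs, putative cholinergic
interneurons) recorded while subjects perform interval-timing tasks. TANs fire
tonically at ~5–6 spikes/s and respond to motivationally salient events with a
brief, stereotyped **pause** in firing. This package implements, as a tested
and reusable pipeline, the analyses needed to characterize those pauses in a
self-timed movement task (and its Pavlovian control): session data model,
synthetic session generation with known ground truth, sliding-window pause
detection, fixed-window response-magnitude rating, and the group-level
statistics that relate TAN responses to interval duration, movement timing,
reward history and striatal region.

It is written for electrophysiologists and methods developers who need a
transparent, fully seeded reference implementation of this analysis chain —
every stage can be exercised end-to-end on synthetic data with programmed
effects, so each statistic can be validated against ground truth before it
touches real recordings.

## The task and the core algorithm

In the time-estimation task (TET) a cue at one of two locations instructs a
minimum waiting period *T* (short or long, e.g. 1.3/2.3 s) from cue onset. The
subject must release a bar only after *T* has elapsed (within a 2 s limited
hold) and touch a target within 1 s; correct trials are rewarded at target
contact, error trials repeat the same cue. The movement onset time
(MOT = release − cue) shows the **scalar property** of timing:
SD(MOT) ∝ mean(MOT), i.e. a constant Weber fraction.

Pause detection follows a sliding-window nonparametric procedure. For a unit
with spike train aligned to an event (cue, movement, contact or reward):

- a 100 ms test window advances in 10 ms steps across the first second after
  the event;
- at each step, per-trial spike rates in the test window are compared with
  rates in the 500 ms immediately preceding cue onset (the control period)
  using a Dunn-type rank z statistic (normal approximation with tie and
  continuity corrections), at p < 0.01 per step;
- a modulation requires ≥ 5 consecutive significant steps in the same
  direction; its onset is the start of the first such run, its offset the end
  of that run plus one window width.

Response magnitude is then rated for **every** unit — responsive or not — in
fixed per-subject quantification windows (e.g. 93–309 ms after the cue) as the
percent change from baseline:

    magnitude = 100 × (window_rate − baseline_rate) / baseline_rate

so a full pause rates −100%. These magnitudes feed the group statistics:
uncorrected Pearson χ² for proportions of responsive neurons, Wilcoxon
rank-sum / signed-rank z tests for magnitude contrasts, linear + Spearman
trends of magnitude against MOT (and against position within runs of ≥ 5
consecutive correct trials), 500-ms MOT binning, and motor vs associative
striatum contrasts.

## Worked example

```r
library(tanlab)

s <- generate_session("monkeyC_TET", n_units = 12, n_trials = 120, seed = 42)
s
#> <tan_session> TET task, 120 trials, 12 units, 40950 spikes

summarize_behavior(s, block_size = 40)
#> <behavior_summary>
#>   interval  n     mean        sd        cv
#> 1    short 55 1.662247 0.2470979 0.1486530
#> 2     long 64 2.626582 0.3593311 0.1368056
#> overall % correct: 87.5
```

The two intervals have nearly equal MOT coefficients of variation (0.149 vs
0.137) — the scalar signature — and the pooled correct rate sits near the
preset's calibrated ~89%. Detection then flags the units with significant
cue-aligned pauses:

```r
det <- detect_pauses(s, scan_config(), intervals = c("short", "long"))
subset(det, direction == "decrease")
#>  unit_id align_event interval n_trials pause_onset_ms pause_offset_ms direction
#>     u001      cue_on    short       55             60             380  decrease
#>     u004      cue_on    short       55            310             450  decrease
#>     u005      cue_on    short       55             30             340  decrease
#>     u006      cue_on    short       55             90             240  decrease
#>     u006      cue_on     long       65             50             360  decrease
#>     u007      cue_on    short       55             70             370  decrease
```

Most detected pauses are interval-selective (here mostly short), matching the
generator's programmed mixture. Magnitudes over the TAN subset, rated in the
93–309 ms preset window regardless of individual responsiveness:

```r
tan_ids <- s$units$unit_id[s$units$label == "TAN"]
m <- magnitude_table(s, "cue_on", unit_ids = tan_ids)
aggregate(magnitude ~ interval, m, mean)
#>   interval magnitude
#> 1     long -12.42614
#> 2    short -37.07259

wide <- merge(m[m$interval == "short", c("unit_id", "magnitude")],
              m[m$interval == "long",  c("unit_id", "magnitude")],
              by = "unit_id")
rank_compare(wide$magnitude.x, wide$magnitude.y, paired = TRUE)
#> z = -1.050, p = 0.294, n = 8
```

A deeper mean depression on short-interval trials (−37% vs −12% below
baseline), not significant across only 8 TANs — exactly the kind of
within-neuron interval contrast the pipeline runs at scale.
`run_pipeline(preset = "monkeyC_TET", seed = 1, out_dir = "run1")` executes
the whole chain and writes every stage's output (session files, behavior
summary, classifications, detections, magnitudes, group statistics,
provenance) to disk.

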