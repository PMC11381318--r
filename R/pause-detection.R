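#' Sliding-window scan configuration
#'
#' Parameters of the pause-detection procedure: a 100 ms test window is
#' advanced in 10 ms steps across the scan span after the alignment event,
#' and the spike rate in each test window is compared against the rate in
#' the 500 ms immediately preceding cue onset (the control period) with a
#' rank-based z test at `alpha` per step. A modulation requires at least
#' `min_run` consecutive significant steps in the same direction; its
#' onset is the start of the first such run. The control period is always
#' pre-cue, also for movement- and reward-aligned scans.
#'
#' @param align_event Event to align on: `"cue_on"`, `"bar_release"`,
#'   `"target_contact"` or `"reward"`.
#' @param window_ms Test window duration, ms.
#' @param step_ms Step increment, ms.
#' @param control_window_ms Control window in ms relative to cue onset,
#'   half-open.
#' @param alpha Per-step significance level.
#' @param min_run Minimum number of consecutive significant steps.
#' @param scan_span_ms Scanned extent in ms relative to the event; test
#'   windows start at `scan_span_ms[1], +step_ms, ...` and must end within
#'   the span.
#' @param adjust `"none"` (default: alpha applies per comparison, the run
#'   rule providing multiplicity control) or `"bonferroni"` across steps
#'   for sensitivity analysis.
#' @return List of class `scan_config`.
#' @export
scan_config <- function(align_event = "cue_on", window_ms = 100, step_ms = 10,
                        control_window_ms = c(-500, 0), alpha = 0.01,
                        min_run = 5, scan_span_ms = c(0, 1000),
                        adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  if (window_ms <= 0 || step_ms <= 0) stop("window_ms and step_ms must be > 0")
  if (min_run < 1) stop("min_run must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)")
  structure(list(align_event = align_event, window_ms = window_ms,
                 step_ms = step_ms, control_window_ms = control_window_ms,
                 alpha = alpha, min_run = min_run,
                 scan_span_ms = scan_span_ms, adjust = adjust),
            class = "scan_config")
}

#' Per-trial spike counts in an event-aligned window
#'
#' Counts spikes in `[event + window[1], event + window[2])` ms for every
#' event; half-open, so a spike exactly at the window end is not counted.
#'
#' @param times Sorted spike times (s).
#' @param event_times Event times (s); `NA` events are dropped.
#' @param window_ms Length-2 window in ms relative to the event.
#' @return Integer vector, one count per event.
#' @export
aligned_counts <- function(times, event_times, window_ms) {
  event_times <- event_times[!is.na(event_times)]
  if (length(event_times) == 0) stop("empty event list")
  a <- event_times + window_ms[1] / 1000
  b <- event_times + window_ms[2] / 1000
  findInterval(b, times, left.open = TRUE) -
    findInterval(a, times, left.open = TRUE)
}

# rank-sum z with tie and continuity correction on pooled ranks;
# returns list(z, p); z > 0 means x tends larger than y
rank_z <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  E <- n1 * (N + 1) / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties)
  V <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (V <= 0) return(list(z = 0, p = 1))
  d <- W - E
  z <- sign(d) * max(0, abs(d) - 0.5) / sqrt(V)
  list(z = z, p = min(1, 2 * stats::pnorm(-abs(z))))
}

#' Rank-based comparison of one test window against the control period
#'
#' The Dunn-type step test of the sliding-window procedure: spike counts
#' are converted to rates (count/duration), the test-window rates are
#' compared with the control-period rates through the ranks of the pooled
#' sample, and a z statistic with tie and continuity correction is
#' evaluated against the normal distribution (two-sided). Rank tests are
#' scale invariant, so using rates rather than counts affects only
#' reporting. The two samples may have different sizes: [pause_scan()]
#' tiles the control period into subwindows of the test-window length so
#' that both samples have identical count granularity under the null (a
#' rank test between counts collected over unequal durations is not
#' exchangeable under the null and spuriously favors "decrease"; see the
#' methods vignette).
#'
#' @param control_counts,test_counts Spike-count samples (control: per
#'   trial and control subwindow; test: per trial).
#' @param control_dur_s,test_dur_s Durations (s) of the windows the counts
#'   were collected in.
#' @param alpha Significance level.
#' @return List: `statistic` (z of test vs control), `p`, `significant`,
#'   `direction` (`"decrease"`, `"increase"` or `"none"`).
#' @export
stepwise_test <- function(control_counts, test_counts,
                          control_dur_s = 0.1, test_dur_s = 0.1,
                          alpha = 0.01) {
  rz <- rank_z(test_counts / test_dur_s, control_counts / control_dur_s)
  sig <- rz$p < alpha && rz$z != 0
  list(statistic = rz$z, p = rz$p, significant = sig,
       direction = if (!sig) "none" else if (rz$z < 0) "decrease" else "increase")
}

# first maximal run of >= min_run consecutive TRUEs; returns c(start, end)
# indices or NULL
first_long_run <- function(flags, min_run) {
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= min_run)
  if (!length(hit)) return(NULL)
  c(starts[hit[1]], ends[hit[1]])
}

#' Sliding-window pause scan
#'
#' Runs [stepwise_test()] at every step of the scan span and locates
#' modulations: the pause onset is the start time of the first run of at
#' least `min_run` consecutive steps with a significant rate decrease; the
#' offset is the start of the last step of that maximal run plus the
#' window duration. Significant increases are tracked symmetrically so
#' rebounds can be reported. The control period is taken relative to
#' `cue_times` regardless of the alignment event.
#'
#' @param times Sorted spike times (s).
#' @param event_times Alignment-event times (s), one per trial; `NA`
#'   trials are dropped (from the control sample too, keeping the samples
#'   paired by trial).
#' @param cue_times Cue-onset times (s) defining the control period.
#' @param config A [scan_config()].
#' @return List of class `sliding_scan`: `steps` (data.frame: start_ms,
#'   rate, statistic, p, sig_decrease, sig_increase), `pause_onset_ms`,
#'   `pause_offset_ms`, `increase_onset_ms`, `increase_offset_ms`,
#'   `direction`, `n_trials`.
#' @export
pause_scan <- function(times, event_times, cue_times,
                       config = scan_config()) {
  stopifnot(inherits(config, "scan_config"))
  ok <- !is.na(event_times)
  event_times <- event_times[ok]
  cue_times <- cue_times[ok]
  if (length(event_times) == 0) stop("no usable trials")
  span <- config$scan_span_ms
  starts <- seq(span[1], span[2] - config$window_ms, by = config$step_ms)
  if (length(starts) < config$min_run) {
    stop("scan span too short: fewer than min_run steps")
  }
  # tile the control period into subwindows of the test-window length so
  # control and test counts share the same null distribution
  n_sub <- max(1L, floor(diff(config$control_window_ms) / config$window_ms))
  sub_starts <- config$control_window_ms[1] + (seq_len(n_sub) - 1L) * config$window_ms
  ctrl <- unlist(lapply(sub_starts, function(c0) {
    aligned_counts(times, cue_times, c(c0, c0 + config$window_ms))
  }))
  ctrl_dur <- config$window_ms / 1000
  test_dur <- config$window_ms / 1000
  alpha <- if (config$adjust == "bonferroni") {
    config$alpha / length(starts)
  } else config$alpha

  res <- lapply(starts, function(s0) {
    cnt <- aligned_counts(times, event_times, c(s0, s0 + config$window_ms))
    st <- stepwise_test(ctrl, cnt, ctrl_dur, test_dur, alpha)
    data.frame(start_ms = s0, rate = mean(cnt) / test_dur,
               statistic = st$statistic, p = st$p,
               sig_decrease = st$direction == "decrease",
               sig_increase = st$direction == "increase")
  })
  steps <- do.call(rbind, res)

  dec <- first_long_run(steps$sig_decrease, config$min_run)
  inc <- first_long_run(steps$sig_increase, config$min_run)
  mk <- function(run) {
    if (is.null(run)) c(NA_real_, NA_real_)
    else c(steps$start_ms[run[1]], steps$start_ms[run[2]] + config$window_ms)
  }
  d <- mk(dec); i <- mk(inc)
  structure(list(
    steps = steps,
    pause_onset_ms = d[1], pause_offset_ms = d[2],
    increase_onset_ms = i[1], increase_offset_ms = i[2],
    direction = if (!is.null(dec)) "decrease"
                else if (!is.null(inc)) "increase" else "none",
    n_trials = length(event_times), config = config
  ), class = "sliding_scan")
}

#' @export
print.sliding_scan <- function(x, ...) {
  cat(sprintf("<sliding_scan> %s, %d trials, direction: %s",
              x$config$align_event, x$n_trials, x$direction))
  if (!is.na(x$pause_onset_ms)) {
    cat(sprintf(", pause %g-%g ms", x$pause_onset_ms, x$pause_offset_ms))
  }
  cat("\n")
  invisible(x)
}

#' Detect pauses for every unit of a session
#'
#' Convenience wrapper running [pause_scan()] per unit and per interval
#' (plus pooled intervals as `"all"`). Reward-aligned scans use rewarded
#' trials only (reward exists only there).
#'
#' @param s A `tan_session`.
#' @param config A [scan_config()].
#' @param intervals Conditions to scan; subset of
#'   `c("short", "long", "all")`.
#' @return data.frame: unit_id, align_event, interval, n_trials,
#'   pause_onset_ms, pause_offset_ms, direction.
#' @export
detect_pauses <- function(s, config = scan_config(),
                          intervals = c("short", "long", "all")) {
  ev_all <- event_times_of(s$trials, config$align_event)
  cue_all <- s$trials$t_cue_on
  out <- list()
  for (uid in s$units$unit_id) {
    times <- unit_spikes(s, uid)
    for (iv in intervals) {
      sel <- if (iv == "all") rep(TRUE, nrow(s$trials)) else s$trials$interval == iv
      sel <- sel & !is.na(ev_all)
      if (!any(sel)) next
      sc <- pause_scan(times, ev_all[sel], cue_all[sel], config)
      out[[length(out) + 1L]] <- data.frame(
        unit_id = uid, align_event = config$align_event, interval = iv,
        n_trials = sc$n_trials, pause_onset_ms = sc$pause_onset_ms,
        pause_offset_ms = sc$pause_offset_ms, direction = sc$direction,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Derive a fixed quantification window from detected pauses
#'
#' Summarizes a population of detected pause onsets/offsets into one fixed
#' window in which response magnitude is rated for all units. `"mean"`
#' takes the average onset and offset; `"central_coverage"` takes the
#' quantile window containing the central `coverage` fraction of onsets
#' and offsets, so that the window includes most pause onset and offset
#' times.
#'
#' @param onsets_ms,offsets_ms Detected pause onsets/offsets, ms.
#' @param method `"mean"` or `"central_coverage"`.
#' @param coverage Central fraction for `"central_coverage"`.
#' @return List of class `quant_window`: `start_ms`, `end_ms`,
#'   `provenance = "derived"`.
#' @export
derive_quant_window <- function(onsets_ms, offsets_ms,
                                method = c("mean", "central_coverage"),
                                coverage = 0.9) {
  method <- match.arg(method)
  onsets_ms <- onsets_ms[!is.na(onsets_ms)]
  offsets_ms <- offsets_ms[!is.na(offsets_ms)]
  if (!length(onsets_ms) || !length(offsets_ms)) {
    stop("need at least one detected pause")
  }
  w <- if (method == "mean") {
    c(mean(onsets_ms), mean(offsets_ms))
  } else {
    c(stats::quantile(onsets_ms, (1 - coverage) / 2, names = FALSE),
      stats::quantile(offsets_ms, (1 + coverage) / 2, names = FALSE))
  }
  if (w[1] >= w[2]) stop("derived window is empty")
  structure(list(start_ms = w[1], end_ms = w[2], provenance = "derived"),
            class = "quant_window")
}

#' Preset quantification windows
#'
#' The fixed per-monkey, per-event rating windows (ms after the event)
#' established from the average latency and duration of detected pauses:
#' cue windows 93-309 ms (monkey C, both intervals) and 127-313 /
#' 211-418 ms (monkey D, short/long); reward windows 139-369 ms (C) and
#' 194-391 ms (D), both intervals.
#'
#' @param monkey `"C"` or `"D"`.
#' @param event `"cue_on"` or `"reward"`.
#' @param interval `"short"` or `"long"`.
#' @return List of class `quant_window` with `provenance = "preset"`.
#' @export
quant_window_preset <- function(monkey = c("C", "D"),
                                event = c("cue_on", "reward"),
                                interval = c("short", "long")) {
  monkey <- match.arg(monkey)
  event <- match.arg(event)
  interval <- match.arg(interval)
  w <- if (event == "cue_on") {
    if (monkey == "C") c(93, 309)
    else if (interval == "short") c(127, 313) else c(211, 418)
  } else {
    if (monkey == "C") c(139, 369) else c(194, 391)
  }
  structure(list(start_ms = w[1], end_ms = w[2], provenance = "preset"),
            class = "quant_window")
}
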