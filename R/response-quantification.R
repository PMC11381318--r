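#' Response magnitude in a fixed window
#'
#' Signed percent change of the mean event-aligned rate relative to
#' baseline: `100 * (window_rate - baseline_rate) / baseline_rate`.
#' Negative values are decreases (pauses); a fully silenced window rates
#' -100%. Rated for every unit irrespective of individual responsiveness.
#'
#' @param times Sorted spike times (s).
#' @param event_times Alignment-event times (s).
#' @param window A `quant_window` or length-2 numeric (ms).
#' @param baseline_rate Baseline rate in spikes/s (> 0).
#' @return Percent change (scalar).
#' @export
response_magnitude <- function(times, event_times, window, baseline_rate) {
  if (baseline_rate <= 0) stop("undefined magnitude: baseline_rate must be > 0")
  w <- if (inherits(window, "quant_window")) c(window$start_ms, window$end_ms)
       else as.numeric(window)
  cnt <- aligned_counts(times, event_times, w)
  rate <- mean(cnt) / (diff(w) / 1000)
  100 * (rate - baseline_rate) / baseline_rate
}

#' Magnitude table over units and conditions
#'
#' One row per unit x interval condition, using the per-monkey fixed
#' quantification windows (presets by default) and a baseline computed
#' from the same condition's trials' pre-cue control period. For
#' reward-aligned tables only rewarded trials enter (reward exists only
#' there). Conditions with zero usable trials are omitted with a warning.
#'
#' @param s A `tan_session`.
#' @param align_event `"cue_on"` or `"reward"` (presets exist for these),
#'   or any event when `windows` is supplied.
#' @param windows Optional named list `list(short = , long = )` of
#'   `quant_window`s overriding the presets.
#' @param rewarded_only Restrict to rewarded (correct) trials; defaults to
#'   `TRUE` for reward alignment.
#' @param unit_ids Units to include (default: all).
#' @return data.frame of class `magnitude_table`: unit_id, align_event,
#'   interval, baseline_rate, window_rate, magnitude, n_trials.
#' @export
magnitude_table <- function(s, align_event = "cue_on", windows = NULL,
                            rewarded_only = align_event == "reward",
                            unit_ids = NULL) {
  if (is.null(unit_ids)) unit_ids <- s$units$unit_id
  mk <- unique(s$units$monkey)
  ev_all <- event_times_of(s$trials, align_event)
  out <- list()
  outc <- s$trials$outcome
  if (all(is.na(outc))) outc <- classify_outcomes(s$trials, s$config)
  for (iv in c("short", "long")) {
    sel <- s$trials$interval == iv & !is.na(ev_all)
    if (rewarded_only) sel <- sel & outc == "correct"
    if (!any(sel)) {
      warning("no usable trials for interval ", iv, "; rows omitted")
      next
    }
    w <- if (!is.null(windows)) windows[[iv]] else {
      if (length(mk) != 1 || !mk %in% c("C", "D")) {
        stop("no preset windows for this session; supply `windows`")
      }
      quant_window_preset(mk, if (align_event == "cue_on") "cue_on" else "reward",
                          iv)
    }
    wv <- c(w$start_ms, w$end_ms)
    for (uid in unit_ids) {
      times <- unit_spikes(s, uid)
      base <- baseline_rate_estimate(times, s$trials$t_cue_on[sel])
      if (base <= 0) next
      cnt <- aligned_counts(times, ev_all[sel], wv)
      rate <- mean(cnt) / (diff(wv) / 1000)
      out[[length(out) + 1L]] <- data.frame(
        unit_id = uid, align_event = align_event, interval = iv,
        baseline_rate = base, window_rate = rate,
        magnitude = 100 * (rate - base) / base, n_trials = sum(sel),
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, out)
  class(tab) <- c("magnitude_table", class(tab))
  tab
}

#' Per-trial response magnitudes
#'
#' Single-trial version of [response_magnitude()] (`n_trials = 1` per
#' row), feeding the MOT-trend and consecutive-correct-sequence analyses.
#' The baseline is the unit's rate over the pre-cue control period of the
#' same trial set.
#'
#' @param s A `tan_session`.
#' @param align_event Alignment event.
#' @param windows Optional per-interval window override (see
#'   [magnitude_table()]).
#' @param unit_ids Units to include.
#' @return data.frame: unit_id, trial_index, interval, mot, magnitude.
#' @export
trial_magnitudes <- function(s, align_event = "cue_on", windows = NULL,
                             unit_ids = NULL) {
  if (is.null(unit_ids)) unit_ids <- s$units$unit_id
  mk <- unique(s$units$monkey)
  ev_all <- event_times_of(s$trials, align_event)
  mot <- compute_mot(s$trials)
  out <- list()
  for (iv in c("short", "long")) {
    sel <- which(s$trials$interval == iv & !is.na(ev_all))
    if (!length(sel)) next
    w <- if (!is.null(windows)) windows[[iv]] else {
      quant_window_preset(mk, if (align_event == "cue_on") "cue_on" else "reward",
                          iv)
    }
    wv <- c(w$start_ms, w$end_ms)
    dur_s <- diff(wv) / 1000
    for (uid in unit_ids) {
      times <- unit_spikes(s, uid)
      base <- baseline_rate_estimate(times, s$trials$t_cue_on[sel])
      if (base <= 0) next
      cnt <- aligned_counts(times, ev_all[sel], wv)
      out[[length(out) + 1L]] <- data.frame(
        unit_id = uid, trial_index = s$trials$trial_index[sel],
        interval = iv, mot = mot[sel],
        magnitude = 100 * (cnt / dur_s - base) / base,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# gaussian smoothing with edge-renormalized kernel; sigma in bins
gauss_smooth <- function(x, sigma_bins) {
  if (sigma_bins <= 0) return(x)
  half <- ceiling(4 * sigma_bins)
  k <- stats::dnorm(-half:half, sd = sigma_bins)
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- max(1, i - half):min(n, i + half)
    kk <- k[j - i + half + 1]
    out[i] <- sum(x[j] * kk) / sum(kk)
  }
  out
}

#' Population activity curve
#'
#' Event-aligned population PSTH: each unit's trial-averaged rate is
#' computed in nonoverlapping 10 ms bins, then averaged across units with
#' the SEM over units. Optional Gaussian smoothing (sigma in bins,
#' edge-renormalized kernel, applied per unit before aggregation) for
#' region-comparison curves.
#'
#' @param s A `tan_session`.
#' @param unit_ids Units to aggregate (>= 2 for a meaningful SEM).
#' @param align_event Alignment event.
#' @param span_ms Length-2 span in ms relative to the event.
#' @param bin_ms Bin width, ms.
#' @param sigma_bins Gaussian smoothing sigma in bins; 0 = none.
#' @param trial_sel Optional logical vector selecting trials.
#' @return data.frame of class `population_curve`: bin_start_ms,
#'   mean_rate, sem, n_units.
#' @export
population_curve <- function(s, unit_ids = NULL, align_event = "cue_on",
                             span_ms = c(-500, 1000), bin_ms = 10,
                             sigma_bins = 0, trial_sel = NULL) {
  if (is.null(unit_ids)) unit_ids <- s$units$unit_id
  if (!length(unit_ids)) stop("empty unit set")
  ev <- event_times_of(s$trials, align_event)
  if (!is.null(trial_sel)) ev <- ev[trial_sel]
  ev <- ev[!is.na(ev)]
  edges <- seq(span_ms[1], span_ms[2], by = bin_ms)
  starts <- edges[-length(edges)]
  bin_s <- bin_ms / 1000
  curves <- vapply(unit_ids, function(uid) {
    times <- unit_spikes(s, uid)
    rates <- vapply(starts, function(b) {
      mean(aligned_counts(times, ev, c(b, b + bin_ms))) / bin_s
    }, numeric(1))
    gauss_smooth(rates, sigma_bins)
  }, numeric(length(starts)))
  curves <- matrix(curves, nrow = length(starts))
  n_u <- length(unit_ids)
  out <- data.frame(
    bin_start_ms = starts,
    mean_rate = rowMeans(curves),
    sem = if (n_u > 1) apply(curves, 1, stats::sd) / sqrt(n_u) else 0,
    n_units = n_u
  )
  class(out) <- c("population_curve", class(out))
  out
}
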