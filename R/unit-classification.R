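#' Classifier rule for TAN/PAN labelling
#'
#' Units are labelled from their baseline firing rate and spike width:
#' TANs show a higher tonic rate and broader spikes than the phasically
#' active projection neurons (PANs). A unit must satisfy both criteria of
#' a class to receive its label; anything in the overlap band is left
#' `unclassified`. Rate thresholds default to midpoints between the
#' reported per-class means; width thresholds differ strongly between
#' subjects, so [default_classifier_rule()] provides per-monkey presets.
#'
#' @param min_tan_rate Minimum TAN rate, spikes/s.
#' @param max_pan_rate Maximum PAN rate, spikes/s.
#' @param min_tan_width Minimum TAN spike width, microseconds.
#' @param max_pan_width Maximum PAN spike width, microseconds.
#' @return List of class `classifier_rule`.
#' @export
classifier_rule <- function(min_tan_rate = 3.5, max_pan_rate = 2.5,
                            min_tan_width = 800, max_pan_width = 800) {
  if (max_pan_rate > min_tan_rate) stop("max_pan_rate must be <= min_tan_rate")
  structure(list(min_tan_rate = min_tan_rate, max_pan_rate = max_pan_rate,
                 min_tan_width = min_tan_width, max_pan_width = max_pan_width),
            class = "classifier_rule")
}

#' Per-monkey default classifier rules
#'
#' Width thresholds sit between the per-class mean spike widths of each
#' subject (monkey C: TAN 905, PAN 758 microseconds; monkey D: TAN 1220,
#' PAN 656).
#'
#' @param monkey `"C"` or `"D"`.
#' @return A [classifier_rule()].
#' @export
default_classifier_rule <- function(monkey = c("C", "D")) {
  monkey <- match.arg(monkey)
  if (monkey == "C") classifier_rule(3.5, 2.5, 800, 800)
  else classifier_rule(3.5, 2.5, 940, 940)
}

#' Baseline firing rate over the pre-cue control period
#'
#' Total spikes in the control window across trials divided by total
#' control time. The control period is the 500 ms immediately preceding
#' cue onset; windows are half-open `[start, end)` in ms relative to the
#' cue.
#'
#' @param times Sorted spike times (s).
#' @param cue_times Cue-onset times (s), one per trial.
#' @param control_window_ms Length-2 window in ms relative to cue onset.
#' @return Rate in spikes/s.
#' @export
baseline_rate_estimate <- function(times, cue_times,
                                   control_window_ms = c(-500, 0)) {
  cue_times <- cue_times[!is.na(cue_times)]
  dur_s <- diff(control_window_ms) / 1000
  if (length(cue_times) == 0 || dur_s <= 0) stop("zero control time")
  counts <- aligned_counts(times, cue_times, control_window_ms)
  sum(counts) / (length(cue_times) * dur_s)
}

#' Classify one unit from rate and width
#'
#' @param rate Baseline rate, spikes/s.
#' @param width Spike width, microseconds.
#' @param rule A [classifier_rule()].
#' @return `"TAN"`, `"PAN"` or `"unclassified"`.
#' @export
classify_unit <- function(rate, width, rule = classifier_rule()) {
  if (rate >= rule$min_tan_rate && width >= rule$min_tan_width) "TAN"
  else if (rate <= rule$max_pan_rate && width <= rule$max_pan_width) "PAN"
  else "unclassified"
}

#' Classify every unit of a session
#'
#' Estimates each unit's baseline rate over the pre-cue control period and
#' applies the rule to rate and recorded spike width. Task responsiveness
#' is deliberately not used, keeping classification independent of pause
#' detection.
#'
#' @param s A `tan_session`.
#' @param rule A [classifier_rule()]; default chosen by the session's
#'   monkey where recognized.
#' @return data.frame: unit_id, measured_rate, spike_width, label.
#' @export
classify_units <- function(s, rule = NULL) {
  if (is.null(rule)) {
    mk <- unique(s$units$monkey)
    rule <- if (length(mk) == 1 && mk %in% c("C", "D")) {
      default_classifier_rule(mk)
    } else classifier_rule()
  }
  cue <- s$trials$t_cue_on
  res <- lapply(seq_len(nrow(s$units)), function(i) {
    u <- s$units[i, ]
    r <- baseline_rate_estimate(unit_spikes(s, u$unit_id), cue)
    data.frame(unit_id = u$unit_id, measured_rate = r,
               spike_width = u$spike_width,
               label = classify_unit(r, u$spike_width, rule),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
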