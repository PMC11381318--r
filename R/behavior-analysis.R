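#' Movement onset time
#'
#' MOT is the time between cue onset and bar release. Vectorized over a
#' trial table; trials without a release yield `NA`.
#'
#' @param trials Trial-event data.frame (see [session()]).
#' @return Numeric vector of MOTs in seconds.
#' @export
compute_mot <- function(trials) {
  trials$t_bar_release - trials$t_cue_on
}

#' Classify trial outcomes under the task rules
#'
#' A trial is `correct` when the bar is released after the interval's time
#' threshold but within the limited hold, and the target is contacted within
#' the movement-time limit; `underestimation` when released before the
#' threshold; `late_release` when released after threshold + limited hold;
#' `slow_movement` when the release was timed but the reach exceeded the
#' movement-time limit; `excluded` when the subject never released the bar
#' or never contacted a target. A release exactly at the threshold counts as
#' correct (the waiting period has elapsed). Categories are mutually
#' exclusive and exhaustive. For the Pavlovian task every trial with a cue
#' is `correct` (reward is delivered unconditionally).
#'
#' @param trials Trial-event data.frame.
#' @param config A [task_config()].
#' @return Character vector of outcomes, one per trial.
#' @export
classify_outcomes <- function(trials, config) {
  n <- nrow(trials)
  if (config$task_kind == "PCT") return(rep("correct", n))
  mot <- compute_mot(trials)
  mt <- trials$t_target_contact - trials$t_bar_release
  thr <- interval_threshold(config, trials$interval)
  out <- rep("excluded", n)
  responded <- !is.na(mot) & !is.na(mt)
  early <- responded & mot < thr
  late <- responded & mot > thr + config$limited_hold
  timed <- responded & !early & !late
  slow <- timed & mt > config$movement_time_limit
  out[early] <- "underestimation"
  out[late] <- "late_release"
  out[slow] <- "slow_movement"
  out[timed & !slow] <- "correct"
  out
}

#' Classify the outcome of a single trial
#'
#' @param trial One-row trial data.frame or a list with the trial fields.
#' @param config A [task_config()].
#' @return Outcome string.
#' @export
classify_outcome <- function(trial, config) {
  classify_outcomes(as.data.frame(trial[TRIAL_COLUMNS[TRIAL_COLUMNS %in% names(trial)]]),
                    config)[1]
}

#' Summarize timing behavior
#'
#' Per-interval MOT moments over non-excluded trials, percent-correct per
#' consecutive trial block (per interval and pooled), and overall outcome
#' counts. Blocks are consecutive, non-overlapping, chronological groups of
#' `block_size` trials.
#'
#' @param s A `tan_session` (outcomes are classified on the fly if absent).
#' @param block_size Trials per block (>= 1).
#' @return A list of class `behavior_summary` with elements `mot`
#'   (data.frame: interval, n, mean, sd, cv), `blocks` (data.frame: block,
#'   interval, n, n_correct, pct_correct), `overall_pct_correct`, and
#'   `outcome_counts`.
#' @export
summarize_behavior <- function(s, block_size = 40) {
  if (block_size < 1) stop("block_size must be >= 1")
  tr <- s$trials
  if (all(is.na(tr$outcome))) tr$outcome <- classify_outcomes(tr, s$config)
  mot <- compute_mot(tr)
  keep <- tr$outcome != "excluded"

  mot_tab <- do.call(rbind, lapply(c("short", "long"), function(iv) {
    m <- mot[keep & tr$interval == iv]
    m <- m[!is.na(m)]
    data.frame(interval = iv, n = length(m),
               mean = if (length(m)) mean(m) else NA_real_,
               sd = if (length(m) > 1) stats::sd(m) else NA_real_,
               cv = if (length(m) > 1 && mean(m) > 0) stats::sd(m) / mean(m) else NA_real_,
               stringsAsFactors = FALSE)
  }))

  block <- (seq_len(nrow(tr)) - 1L) %/% as.integer(block_size) + 1L
  blocks <- do.call(rbind, lapply(split(seq_len(nrow(tr)), block), function(idx) {
    do.call(rbind, lapply(c("short", "long", "all"), function(iv) {
      sel <- if (iv == "all") idx else idx[tr$interval[idx] == iv]
      data.frame(block = block[idx[1]], interval = iv, n = length(sel),
                 n_correct = sum(tr$outcome[sel] == "correct"),
                 pct_correct = if (length(sel))
                   100 * mean(tr$outcome[sel] == "correct") else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(blocks) <- NULL

  counts <- table(factor(tr$outcome, levels = OUTCOME_LEVELS))
  structure(list(
    mot = mot_tab,
    blocks = blocks,
    overall_pct_correct = 100 * mean(tr$outcome == "correct"),
    outcome_counts = counts
  ), class = "behavior_summary")
}

#' @export
print.behavior_summary <- function(x, ...) {
  cat("<behavior_summary>\n")
  print(x$mot)
  cat(sprintf("overall %% correct: %.1f\n", x$overall_pct_correct))
  invisible(x)
}

#' Scalar-property diagnostics for two MOT distributions
#'
#' Under scalar (Weber) timing the SD of produced intervals grows in
#' proportion to their mean, so the coefficient of variation is constant
#' across intervals and the SD ratio matches the mean ratio. Descriptive
#' only; no hypothesis test.
#'
#' @param mots_short,mots_long MOT samples in seconds (length >= 2 each).
#' @return List with `cv_short`, `cv_long`, `sd_ratio` (long/short),
#'   `mean_ratio` (long/short).
#' @export
scalar_property_check <- function(mots_short, mots_long) {
  if (length(mots_short) < 2 || length(mots_long) < 2) {
    stop("need at least 2 observations per interval")
  }
  ms <- mean(mots_short); ml <- mean(mots_long)
  if (ms == 0 || ml == 0) stop("degenerate zero-mean MOT distribution")
  list(cv_short = stats::sd(mots_short) / ms,
       cv_long = stats::sd(mots_long) / ml,
       sd_ratio = stats::sd(mots_long) / stats::sd(mots_short),
       mean_ratio = ml / ms)
}
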