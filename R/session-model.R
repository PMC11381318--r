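#' Task configuration
#'
#' Describes one timing-task context: either the self-timed movement task
#' (`"TET"`), in which the subject must release a bar only after a cued
#' minimum waiting period has elapsed, or the Pavlovian variant (`"PCT"`),
#' in which the cue is followed by reward at a fixed delay with no action
#' required. The cue location maps one-to-one onto the interval duration.
#'
#' @param task_kind `"TET"` (time-estimation task) or `"PCT"` (Pavlovian
#'   conditioning task).
#' @param short_threshold,long_threshold Minimum waiting periods (seconds,
#'   measured from cue onset) for the short and long interval. In the PCT
#'   these are the fixed cue-to-reward delays.
#' @param cue_duration Cue presentation time in seconds.
#' @param trial_duration Total trial length in seconds after cue onset.
#' @param limited_hold Maximum time (s) after the threshold within which the
#'   bar must be released for the trial to count as correct.
#' @param movement_time_limit Maximum allowed bar-release-to-target-contact
#'   time (s).
#' @param cue_map Named character vector mapping cue side to interval,
#'   e.g. `c(left = "short", right = "long")`.
#' @return An object of class `task_config`.
#' @export
task_config <- function(task_kind = c("TET", "PCT"),
                        short_threshold = 1.3,
                        long_threshold = 2.3,
                        cue_duration = 0.5,
                        trial_duration = 6.0,
                        limited_hold = 2.0,
                        movement_time_limit = 1.0,
                        cue_map = c(left = "short", right = "long")) {
  task_kind <- match.arg(task_kind)
  cfg <- list(
    task_kind = task_kind,
    short_threshold = as.numeric(short_threshold),
    long_threshold = as.numeric(long_threshold),
    cue_duration = as.numeric(cue_duration),
    trial_duration = as.numeric(trial_duration),
    limited_hold = as.numeric(limited_hold),
    movement_time_limit = as.numeric(movement_time_limit),
    cue_map = cue_map
  )
  class(cfg) <- "task_config"
  durs <- unlist(cfg[c("short_threshold", "long_threshold", "cue_duration",
                       "trial_duration", "limited_hold", "movement_time_limit")])
  if (any(!is.finite(durs)) || any(durs <= 0)) {
    stop("all task durations must be positive and finite")
  }
  if (!(cfg$short_threshold < cfg$long_threshold &&
        cfg$long_threshold < cfg$trial_duration)) {
    stop("need 0 < short_threshold < long_threshold < trial_duration")
  }
  if (!setequal(names(cue_map), c("left", "right")) ||
      !setequal(unname(cue_map), c("short", "long"))) {
    stop("cue_map must map sides {left, right} onto intervals {short, long}")
  }
  cfg
}

#' Interval threshold for a trial
#'
#' @param config A [task_config()].
#' @param interval `"short"` or `"long"` (vectorized).
#' @return Threshold(s) in seconds.
#' @export
interval_threshold <- function(config, interval) {
  ifelse(interval == "short", config$short_threshold, config$long_threshold)
}

TRIAL_COLUMNS <- c("trial_index", "cue_side", "interval", "t_cue_on",
                   "t_bar_release", "t_target_contact", "t_reward", "outcome")
UNIT_COLUMNS <- c("unit_id", "monkey", "region", "ap_position_mm",
                  "baseline_rate", "spike_width", "label")
OUTCOME_LEVELS <- c("correct", "underestimation", "late_release",
                    "slow_movement", "excluded")

#' Assemble a recording session
#'
#' Binds a task configuration, a chronological trial-event table, a unit
#' metadata table and a long-format spike table into one validated object.
#' All event and spike times are absolute seconds on a single session clock;
#' alignment to task events is always computed downstream, never stored.
#'
#' @param config A [task_config()].
#' @param trials data.frame with columns `trial_index, cue_side, interval,
#'   t_cue_on, t_bar_release, t_target_contact, t_reward, outcome`. Missing
#'   events are `NA` (never 0 or -1: 0 is a legal time).
#' @param units data.frame with columns `unit_id, monkey, region,
#'   ap_position_mm, baseline_rate, spike_width, label`. `spike_width` is in
#'   microseconds, `baseline_rate` in spikes/s.
#' @param spikes data.frame with columns `unit_id, time_s`, times sorted
#'   within unit.
#' @param metadata Named list of scalar annotations.
#' @param validate Stop on invariant violations (default `TRUE`).
#' @return An object of class `tan_session`.
#' @export
session <- function(config, trials, units, spikes, metadata = list(),
                    validate = TRUE) {
  trials <- as.data.frame(trials)[, TRIAL_COLUMNS, drop = FALSE]
  units <- as.data.frame(units)[, UNIT_COLUMNS, drop = FALSE]
  spikes <- as.data.frame(spikes)[, c("unit_id", "time_s"), drop = FALSE]
  rownames(trials) <- rownames(units) <- rownames(spikes) <- NULL
  s <- structure(list(config = config, trials = trials, units = units,
                      spikes = spikes, metadata = metadata),
                 class = "tan_session")
  if (validate) {
    v <- validate_session(s)
    if (length(v)) stop("invalid session:\n  ", paste(v, collapse = "\n  "))
  }
  s
}

#' @export
print.tan_session <- function(x, ...) {
  cat(sprintf("<tan_session> %s task, %d trials, %d units, %d spikes\n",
              x$config$task_kind, nrow(x$trials), nrow(x$units),
              nrow(x$spikes)))
  invisible(x)
}

#' Validate a session against its invariants
#'
#' Checks referential integrity (every spike's unit exists), trial ordering
#' and contiguity, event-time ordering within trials, reward/outcome
#' consistency, spike-time sortedness, and unit field ranges. Reports rather
#' than throws.
#'
#' @param s A `tan_session`.
#' @return Character vector of human-readable violations; empty if valid.
#' @export
validate_session <- function(s) {
  v <- character()
  tr <- s$trials
  un <- s$units
  sp <- s$spikes
  if (!inherits(s$config, "task_config")) v <- c(v, "config: not a task_config")

  if (nrow(tr)) {
    if (!identical(tr$trial_index, seq_len(nrow(tr)))) {
      v <- c(v, "trials: trial_index must be contiguous 1..n in order")
    }
    if (is.unsorted(tr$t_cue_on, strictly = TRUE)) {
      v <- c(v, "trials: t_cue_on must be strictly increasing (chronological)")
    }
    bad_int <- !tr$interval %in% c("short", "long")
    if (any(bad_int)) {
      v <- c(v, sprintf("trial %d: interval must be short/long",
                        tr$trial_index[bad_int]))
    }
    has_rel <- !is.na(tr$t_bar_release)
    bad <- has_rel & tr$t_bar_release <= tr$t_cue_on
    if (any(bad)) {
      v <- c(v, sprintf("trial %d: t_bar_release must exceed t_cue_on",
                        tr$trial_index[bad]))
    }
    has_con <- !is.na(tr$t_target_contact)
    bad <- has_rel & has_con & tr$t_target_contact <= tr$t_bar_release
    if (any(bad)) {
      v <- c(v, sprintf("trial %d: t_target_contact must exceed t_bar_release",
                        tr$trial_index[bad]))
    }
    if (!all(is.na(tr$outcome))) {
      bad <- !is.na(tr$outcome) & !tr$outcome %in% OUTCOME_LEVELS
      if (any(bad)) {
        v <- c(v, sprintf("trial %d: unknown outcome", tr$trial_index[bad]))
      }
      bad <- !is.na(tr$outcome) &
        ((tr$outcome == "correct") != !is.na(tr$t_reward))
      if (any(bad)) {
        v <- c(v, sprintf("trial %d: t_reward must be present iff outcome is correct",
                          tr$trial_index[bad]))
      }
    }
  }

  if (nrow(un)) {
    if (anyDuplicated(un$unit_id)) v <- c(v, "units: duplicated unit_id")
    bad <- !is.na(un$baseline_rate) & un$baseline_rate < 0
    if (any(bad)) v <- c(v, sprintf("unit %s: baseline_rate < 0", un$unit_id[bad]))
    bad <- !is.na(un$spike_width) & un$spike_width <= 0
    if (any(bad)) v <- c(v, sprintf("unit %s: spike_width <= 0", un$unit_id[bad]))
    bad <- !un$region %in% c("motor", "associative") & !is.na(un$region)
    if (any(bad)) v <- c(v, sprintf("unit %s: region must be motor/associative",
                                    un$unit_id[bad]))
  }

  if (nrow(sp)) {
    orphan <- setdiff(unique(sp$unit_id), un$unit_id)
    if (length(orphan)) {
      v <- c(v, sprintf("spikes: unit_id %s has no matching unit", orphan))
    }
    for (uid in unique(sp$unit_id)) {
      tt <- sp$time_s[sp$unit_id == uid]
      if (is.unsorted(tt)) v <- c(v, sprintf("unit %s: spike times unsorted", uid))
      if (anyNA(tt)) v <- c(v, sprintf("unit %s: NA spike times", uid))
    }
  }
  v
}

#' Spike times of one unit
#'
#' @param s A `tan_session`.
#' @param unit_id Unit identifier.
#' @return Numeric vector of sorted spike times (seconds, session clock).
#' @export
unit_spikes <- function(s, unit_id) {
  s$spikes$time_s[s$spikes$unit_id == unit_id]
}

fmt6 <- function(x) ifelse(is.na(x), "", sprintf("%.6f", x))

#' Write a session to disk
#'
#' Writes `manifest.json` (config, units, metadata), `trials.csv` and
#' `spikes.csv` into `path`. Output is byte-stable for a fixed session:
#' fixed column order, seconds printed with 6 decimal places, missing
#' events as empty cells.
#'
#' @param s A valid `tan_session`.
#' @param path Directory (created if absent).
#' @return `path`, invisibly.
#' @export
save_session <- function(s, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  cfg <- s$config
  manifest <- list(
    task = cfg$task_kind,
    thresholds = list(short = cfg$short_threshold, long = cfg$long_threshold),
    cue_duration = cfg$cue_duration,
    trial_duration = cfg$trial_duration,
    limited_hold = cfg$limited_hold,
    movement_time_limit = cfg$movement_time_limit,
    cue_map = as.list(cfg$cue_map),
    units = lapply(seq_len(nrow(s$units)), function(i) {
      u <- s$units[i, ]
      list(unit_id = u$unit_id, monkey = u$monkey, region = u$region,
           ap_position_mm = if (is.na(u$ap_position_mm)) NULL else u$ap_position_mm,
           baseline_rate = u$baseline_rate, spike_width = u$spike_width,
           label = u$label)
    }),
    metadata = s$metadata
  )
  json <- jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA, null = "null")
  writeLines(json, file.path(path, "manifest.json"))

  tr <- s$trials
  out <- data.frame(
    trial_index = tr$trial_index,
    cue_side = tr$cue_side,
    interval = tr$interval,
    t_cue_on = fmt6(tr$t_cue_on),
    t_bar_release = fmt6(tr$t_bar_release),
    t_target_contact = fmt6(tr$t_target_contact),
    t_reward = fmt6(tr$t_reward),
    outcome = ifelse(is.na(tr$outcome), "", tr$outcome),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, file.path(path, "trials.csv"), row.names = FALSE,
                   quote = FALSE)
  sp <- data.frame(unit_id = s$spikes$unit_id, time_s = fmt6(s$spikes$time_s),
                   stringsAsFactors = FALSE)
  utils::write.csv(sp, file.path(path, "spikes.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a session from disk
#'
#' Counterpart of [save_session()]: expects `manifest.json`, `trials.csv`
#' and `spikes.csv` under `path`. The loaded session is validated; a
#' violation is an error naming the offending trial or unit.
#'
#' @param path Directory written by [save_session()].
#' @return A validated `tan_session`.
#' @export
load_session <- function(path) {
  files <- file.path(path, c("manifest.json", "trials.csv", "spikes.csv"))
  missing <- files[!file.exists(files)]
  if (length(missing)) stop("missing session files: ",
                            paste(basename(missing), collapse = ", "))
  m <- jsonlite::fromJSON(files[1], simplifyVector = TRUE,
                          simplifyDataFrame = FALSE)
  cfg <- task_config(
    task_kind = m$task,
    short_threshold = m$thresholds$short,
    long_threshold = m$thresholds$long,
    cue_duration = m$cue_duration,
    trial_duration = m$trial_duration,
    limited_hold = m$limited_hold,
    movement_time_limit = m$movement_time_limit,
    cue_map = unlist(m$cue_map)
  )
  units <- do.call(rbind, lapply(m$units, function(u) {
    data.frame(unit_id = u$unit_id, monkey = u$monkey, region = u$region,
               ap_position_mm = if (is.null(u$ap_position_mm)) NA_real_ else u$ap_position_mm,
               baseline_rate = u$baseline_rate, spike_width = u$spike_width,
               label = u$label, stringsAsFactors = FALSE)
  }))
  if (is.null(units)) {
    units <- data.frame(unit_id = character(), monkey = character(),
                        region = character(), ap_position_mm = numeric(),
                        baseline_rate = numeric(), spike_width = numeric(),
                        label = character(), stringsAsFactors = FALSE)
  }
  tr <- utils::read.csv(files[2], stringsAsFactors = FALSE, colClasses = c(
    trial_index = "integer", cue_side = "character", interval = "character",
    t_cue_on = "numeric", t_bar_release = "numeric",
    t_target_contact = "numeric", t_reward = "numeric", outcome = "character"
  ))
  tr$outcome[!is.na(tr$outcome) & tr$outcome == ""] <- NA_character_
  sp <- utils::read.csv(files[3], stringsAsFactors = FALSE,
                        colClasses = c(unit_id = "character", time_s = "numeric"))
  meta <- if (is.null(m$metadata)) list() else m$metadata
  session(cfg, tr, units, sp, metadata = meta)
}
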