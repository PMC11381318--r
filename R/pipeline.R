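#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> behavior -> classify -> detect -> quantify ->
#' stats as one reproducible run. Every stage writes its output to
#' `out_dir` as a file (session directory, `behavior.json`,
#' `classification.csv`, `detections.csv`, `magnitudes.csv`,
#' `stats.json`, `provenance.json`), so any stage can be audited or rerun
#' in isolation. The run is fully deterministic given `seed`.
#'
#' @param preset Session preset (see [generate_session()]), or `NULL` to
#'   analyze an existing session.
#' @param session_path When `preset` is `NULL`, directory of a saved
#'   session to load instead of simulating.
#' @param n_units,n_trials Simulation sizes.
#' @param seed Integer seed fixing every stochastic stage.
#' @param out_dir Output directory.
#' @param block_size Trials per behavior block.
#' @param scan A [scan_config()] for cue-aligned detection.
#' @return Invisibly, a list with the in-memory stage results
#'   (`session`, `behavior`, `classification`, `detections`,
#'   `magnitudes`, `stats`).
#' @export
run_pipeline <- function(preset = "monkeyC_TET", session_path = NULL,
                         n_units = 30, n_trials = 200, seed = 1,
                         out_dir, block_size = 40,
                         scan = scan_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wj <- function(x, f) jsonlite::write_json(
    x, file.path(out_dir, f), auto_unbox = TRUE, digits = NA, pretty = TRUE,
    null = "null", na = "null")

  s <- if (is.null(preset)) {
    if (is.null(session_path)) stop("need a preset or a session_path")
    load_session(session_path)
  } else {
    generate_session(preset, n_units = n_units, n_trials = n_trials,
                     seed = seed)
  }
  save_session(s, file.path(out_dir, "session"))

  beh <- summarize_behavior(s, block_size = block_size)
  wj(list(mot = beh$mot, blocks = beh$blocks,
          overall_pct_correct = beh$overall_pct_correct,
          outcome_counts = as.list(beh$outcome_counts)), "behavior.json")

  cls <- classify_units(s)
  utils::write.csv(cls, file.path(out_dir, "classification.csv"),
                   row.names = FALSE)

  tan_ids <- cls$unit_id[cls$label == "TAN"]
  det_cue <- detect_pauses(s, scan, intervals = c("short", "long"))
  dets <- det_cue
  has_reward <- any(!is.na(s$trials$t_reward))
  if (has_reward) {
    scan_rw <- scan
    scan_rw$align_event <- "reward"
    det_rw <- detect_pauses(s, scan_rw, intervals = c("short", "long"))
    dets <- rbind(det_cue, det_rw)
  }
  utils::write.csv(dets, file.path(out_dir, "detections.csv"),
                   row.names = FALSE)

  mags <- magnitude_table(s, "cue_on", unit_ids = tan_ids)
  if (has_reward) {
    mags <- rbind(mags, magnitude_table(s, "reward", unit_ids = tan_ids))
  }
  utils::write.csv(mags, file.path(out_dir, "magnitudes.csv"),
                   row.names = FALSE)

  # group statistics over the TAN subset
  resp_by <- function(det, iv) {
    d <- det[det$interval == iv & det$unit_id %in% tan_ids, ]
    unique(d$unit_id[d$direction == "decrease"])
  }
  stats_out <- list(seed = seed, n_tan = length(tan_ids))
  for (ev in unique(dets$align_event)) {
    d <- dets[dets$align_event == ev, ]
    r_s <- resp_by(d, "short"); r_l <- resp_by(d, "long")
    n <- length(tan_ids)
    block <- list(
      n_responsive_short = length(r_s), n_responsive_long = length(r_l),
      n_responsive_any = length(union(r_s, r_l)), n_tested = n)
    if (length(r_s) + length(r_l) > 0 && n > 0 &&
        (n - length(r_s)) + (n - length(r_l)) > 0) {
      ct <- prop_chi2(length(r_s), n, length(r_l), n)
      block$selectivity_chi2 <- ct$chi2
      block$selectivity_p <- ct$p
    }
    m <- mags[mags$align_event == ev, ]
    wide <- merge(m[m$interval == "short", c("unit_id", "magnitude")],
                  m[m$interval == "long", c("unit_id", "magnitude")],
                  by = "unit_id", suffixes = c("_short", "_long"))
    if (nrow(wide) > 1) {
      rt <- rank_compare(wide$magnitude_short, wide$magnitude_long,
                         paired = TRUE)
      block$short_vs_long <- list(z = rt$z, p = rt$p, n = rt$n)
      block$mean_magnitude_short = mean(wide$magnitude_short)
      block$mean_magnitude_long = mean(wide$magnitude_long)
    }
    stats_out[[ev]] <- block
  }

  if (s$config$task_kind == "TET") {
    runs <- find_correct_runs(s, min_len = 5)
    stats_out$correct_runs <- list(n_runs = nrow(runs),
                                   max_length = if (nrow(runs)) max(runs$length) else 0)
    if (nrow(runs) && length(tan_ids)) {
      tm_cue <- trial_magnitudes(s, "cue_on", unit_ids = tan_ids)
      st <- tryCatch(sequence_trend(tm_cue, runs), error = function(e) NULL)
      if (!is.null(st)) {
        stats_out$sequence_cue <- list(slope = st$slope, rho = st$rho, p = st$p)
      }
      if (has_reward) {
        tm_rw <- trial_magnitudes(s, "reward", unit_ids = tan_ids)
        st <- tryCatch(sequence_trend(tm_rw, runs), error = function(e) NULL)
        if (!is.null(st)) {
          stats_out$sequence_reward <- list(slope = st$slope, rho = st$rho,
                                            p = st$p)
        }
      }
    }
  }
  wj(stats_out, "stats.json")

  prov <- list(
    package = "tanlab",
    version = as.character(utils::packageVersion("tanlab")),
    seed = seed, preset = preset, n_units = n_units, n_trials = n_trials,
    scan = unclass(scan))
  wj(prov, "provenance.json")

  invisible(list(session = s, behavior = beh, classification = cls,
                 detections = dets, magnitudes = mags, stats = stats_out))
}
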