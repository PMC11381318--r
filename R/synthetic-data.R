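#' Behavioral generator parameters
#'
#' Parameters of the synthetic subject. Movement onset times are drawn per
#' interval from a normal distribution truncated at 0 whose SD is
#' `weber_fraction` times its mean, which is the scalar (Weber) property of
#' interval timing; `weber_fraction = 0` gives perfectly timed, identical
#' MOTs.
#'
#' @param n_trials Number of trials to emit (attempts, including errors).
#' @param mot_mean_short,mot_mean_long Means (s) of the MOT distributions.
#' @param weber_fraction SD/mean of the MOT distributions (>= 0).
#' @param p_no_response Probability of a trial with no bar release
#'   (excluded from analyses).
#' @param movement_time_mean,movement_time_sd Release-to-contact time (s),
#'   truncated normal at 0.
#' @param seed Integer seed; fixes the generated behavior exactly.
#' @return List of class `behavior_params`.
#' @export
behavior_params <- function(n_trials = 200,
                            mot_mean_short,
                            mot_mean_long,
                            weber_fraction = 0.15,
                            p_no_response = 0.01,
                            movement_time_mean = 0.4,
                            movement_time_sd = 0.1,
                            seed = NULL) {
  p <- list(n_trials = as.integer(n_trials),
            mot_mean_short = mot_mean_short, mot_mean_long = mot_mean_long,
            weber_fraction = weber_fraction, p_no_response = p_no_response,
            movement_time_mean = movement_time_mean,
            movement_time_sd = movement_time_sd, seed = seed)
  if (p$n_trials < 1) stop("n_trials must be >= 1")
  if (p$weber_fraction < 0) stop("weber_fraction must be >= 0")
  if (p$p_no_response < 0 || p$p_no_response > 1) stop("p_no_response in [0,1]")
  if (p$mot_mean_short <= 0 || p$mot_mean_long <= 0 ||
      p$movement_time_mean <= 0) stop("means must be positive")
  class(p) <- "behavior_params"
  p
}

# normal truncated at 0 by inverse-CDF; sd = 0 degenerates to the mean
rtrunc0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  p0 <- stats::pnorm(0, mean, sd)
  stats::qnorm(stats::runif(n, p0, 1), mean, sd)
}

#' Event-locked response specification
#'
#' Describes one multiplicative rate modulation of a unit: during
#' `[latency, latency + duration)` ms after `align_event` the baseline rate
#' is multiplied by `rate_factor` (< 1 is a pause, > 1 a rebound or phasic
#' activation). Optional couplings make the per-trial depth depend linearly
#' on that trial's movement onset time (centered at the mean MOT of the
#' affected trials, so the average depth stays at `rate_factor`) or on the
#' trial's 1-based position within a run of consecutive correct trials.
#' Slopes are in percent-magnitude units: magnitude = (factor - 1) * 100.
#'
#' @param align_event One of `"cue_on"`, `"bar_release"`,
#'   `"target_contact"`, `"reward"`.
#' @param latency_ms,duration_ms Window relative to the event, ms.
#' @param rate_factor Multiplier on baseline rate (>= 0).
#' @param interval Optional trial filter: `"short"` or `"long"`.
#' @param outcome Optional trial filter on outcome (e.g. `"correct"`).
#' @param mot_coupling_slope Percent magnitude per second of MOT.
#' @param sequence_coupling_slope Percent magnitude per consecutive-correct
#'   position.
#' @return List of class `response_spec`.
#' @export
response_spec <- function(align_event = c("cue_on", "bar_release",
                                          "target_contact", "reward"),
                          latency_ms, duration_ms, rate_factor,
                          interval = NULL, outcome = NULL,
                          mot_coupling_slope = 0,
                          sequence_coupling_slope = 0) {
  align_event <- match.arg(align_event)
  if (latency_ms < 0) stop("latency_ms must be >= 0")
  if (duration_ms <= 0) stop("duration_ms must be > 0")
  if (rate_factor < 0) stop("rate_factor must be >= 0")
  structure(list(align_event = align_event, latency_ms = latency_ms,
                 duration_ms = duration_ms, rate_factor = rate_factor,
                 interval = interval, outcome = outcome,
                 mot_coupling_slope = mot_coupling_slope,
                 sequence_coupling_slope = sequence_coupling_slope),
            class = "response_spec")
}

#' Synthetic unit parameters
#'
#' @param kind `"TAN"` or `"PAN"`.
#' @param baseline_rate Tonic firing rate, spikes/s (> 0).
#' @param firing_regularity Shape of the gamma-interval renewal process
#'   (>= 1; 1 = Poisson, larger = more regular). TANs fire tonically and
#'   regularly, so the TAN default is 2.
#' @param spike_width Waveform width in microseconds.
#' @param responses List of [response_spec()]s.
#' @param seed Integer seed for this unit's spike train.
#' @return List of class `unit_params`.
#' @export
unit_params <- function(kind = c("TAN", "PAN"), baseline_rate = 6,
                        firing_regularity = if (kind[1] == "TAN") 2 else 1,
                        spike_width = 900, responses = list(), seed = NULL) {
  kind <- match.arg(kind)
  if (baseline_rate <= 0) stop("baseline_rate must be > 0")
  if (firing_regularity < 1) stop("firing_regularity must be >= 1")
  structure(list(kind = kind, baseline_rate = baseline_rate,
                 firing_regularity = firing_regularity,
                 spike_width = spike_width, responses = responses,
                 seed = seed),
            class = "unit_params")
}

# pre-cue bar-hold time, and inter-trial gap appended after each trial
PRE_CUE_S <- 1.0
ITI_S <- 1.0

#' Generate task behavior
#'
#' Emits a chronological trial-event table following the task rules: cue
#' sides pseudorandom (balanced within blocks of 10 scheduled trials), an
#' error trial immediately re-queues the same cue side until a rewarded
#' movement is completed, MOT drawn per interval from a truncated normal
#' with SD = weber_fraction x mean, reward delivered at target contact on
#' correct trials. In the Pavlovian task there is no movement and reward is
#' delivered at exactly cue onset + threshold on every trial. Outcomes are
#' filled with the same rules [classify_outcomes()] applies, so
#' reclassification reproduces the generator's bookkeeping exactly.
#'
#' @param config A [task_config()].
#' @param params A [behavior_params()].
#' @return Trial-event data.frame (see [session()]).
#' @export
generate_behavior <- function(config, params) {
  stopifnot(inherits(params, "behavior_params"))
  if (max(params$mot_mean_short, params$mot_mean_long) >= config$trial_duration) {
    stop("infeasible params: mean MOT reaches past the end of the trial")
  }
  if (!is.null(params$seed)) set.seed(params$seed)
  n <- params$n_trials
  sides <- c("left", "right")
  mot_mean <- c(short = params$mot_mean_short, long = params$mot_mean_long)

  # pseudorandom side schedule, balanced within blocks of 10 scheduled trials
  sched <- as.vector(replicate(ceiling(n / 10) + 2,
                               sample(rep(sides, 5))))
  sched_ptr <- 1L

  side_v <- character(n)
  iv_v <- character(n)
  cue_v <- rel_v <- con_v <- rew_v <- rep(NA_real_, n)
  outc_v <- character(n)
  t_start <- 0
  repeat_side <- NULL
  thr <- c(short = config$short_threshold, long = config$long_threshold)
  for (i in seq_len(n)) {
    if (is.null(repeat_side)) {
      side <- sched[sched_ptr]; sched_ptr <- sched_ptr + 1L
    } else {
      side <- repeat_side
    }
    iv <- unname(config$cue_map[[side]])
    t_cue <- t_start + PRE_CUE_S
    if (config$task_kind == "PCT") {
      rew_v[i] <- t_cue + thr[[iv]]
      outc <- "correct"
    } else if (stats::runif(1) < params$p_no_response) {
      outc <- "excluded"
    } else {
      mot <- rtrunc0(1, mot_mean[[iv]], params$weber_fraction * mot_mean[[iv]])
      mt <- rtrunc0(1, params$movement_time_mean, params$movement_time_sd)
      rel_v[i] <- t_cue + mot
      con_v[i] <- rel_v[i] + mt
      outc <- if (mot < thr[[iv]]) "underestimation"
        else if (mot > thr[[iv]] + config$limited_hold) "late_release"
        else if (mt > config$movement_time_limit) "slow_movement"
        else "correct"
      if (outc == "correct") rew_v[i] <- con_v[i]
    }
    side_v[i] <- side
    iv_v[i] <- iv
    cue_v[i] <- t_cue
    outc_v[i] <- outc
    repeat_side <- if (outc == "correct") NULL else side
    t_start <- t_cue + config$trial_duration + ITI_S
  }
  data.frame(trial_index = seq_len(n), cue_side = side_v, interval = iv_v,
             t_cue_on = cue_v, t_bar_release = rel_v, t_target_contact = con_v,
             t_reward = rew_v, outcome = outc_v, stringsAsFactors = FALSE)
}

# 1-based position of each trial within its run of consecutive correct
# trials; NA for non-correct trials
correct_run_position <- function(outcomes) {
  pos <- rep(NA_real_, length(outcomes))
  run <- 0
  for (i in seq_along(outcomes)) {
    if (!is.na(outcomes[i]) && outcomes[i] == "correct") {
      run <- run + 1
      pos[i] <- run
    } else {
      run <- 0
    }
  }
  pos
}

event_times_of <- function(trials, align_event) {
  col <- switch(align_event, cue_on = "t_cue_on", bar_release = "t_bar_release",
                target_contact = "t_target_contact", reward = "t_reward",
                stop("unknown align_event: ", align_event))
  trials[[col]]
}

#' Generate a spike train
#'
#' Baseline firing is a gamma-interval renewal process (shape =
#' `firing_regularity`, mean rate = `baseline_rate`). Rate modulation is
#' applied by thinning: each baseline spike falling in an active response
#' window is kept with probability equal to the product of the active
#' factors (capped at 1); where the combined factor exceeds 1, extra
#' Poisson spikes at the surplus rate are superposed. Thinning preserves
#' the empirical rate ratio exactly in expectation, so an injected factor f
#' yields an aligned-window rate of f x baseline.
#'
#' @param unit A [unit_params()].
#' @param trials Chronological trial-event data.frame (outcomes classified
#'   on the fly when absent).
#' @param config A [task_config()].
#' @return Sorted numeric vector of spike times (seconds, session clock).
#' @export
generate_spike_train <- function(unit, trials, config) {
  stopifnot(inherits(unit, "unit_params"))
  if (!is.null(unit$seed)) set.seed(unit$seed)
  t_end <- max(trials$t_cue_on) + config$trial_duration + ITI_S
  lambda <- unit$baseline_rate
  k <- unit$firing_regularity

  n_est <- ceiling(t_end * lambda + 10 * sqrt(t_end * lambda) + 50)
  isi <- stats::rgamma(n_est, shape = k, rate = k * lambda)
  spk <- cumsum(isi)
  while (length(spk) && spk[length(spk)] < t_end) {
    isi <- stats::rgamma(n_est, shape = k, rate = k * lambda)
    spk <- c(spk, spk[length(spk)] + cumsum(isi))
  }
  spk <- spk[spk < t_end]

  outcomes <- trials$outcome
  if (all(is.na(outcomes))) outcomes <- classify_outcomes(trials, config)
  mot <- compute_mot(trials)
  pos <- correct_run_position(outcomes)

  m <- rep(1, length(spk))
  extras <- numeric()
  for (r in unit$responses) {
    ev <- event_times_of(trials, r$align_event)
    ok <- !is.na(ev)
    if (!is.null(r$interval)) ok <- ok & trials$interval == r$interval
    if (!is.null(r$outcome)) ok <- ok & !is.na(outcomes) & outcomes == r$outcome
    if (!any(ok)) next
    f <- rep(r$rate_factor, nrow(trials))
    if (r$mot_coupling_slope != 0) {
      mot_c <- mot - mean(mot[ok], na.rm = TRUE)
      f <- f + (r$mot_coupling_slope / 100) * ifelse(is.na(mot_c), 0, mot_c)
    }
    if (r$sequence_coupling_slope != 0) {
      f <- f + (r$sequence_coupling_slope / 100) *
        ifelse(is.na(pos), 0, pos - 1)
    }
    # pauses stay in [0, 1]; activations stay nonnegative
    f <- if (r$rate_factor <= 1) pmin(pmax(f, 0), 1) else pmax(f, 0)
    dur_s <- r$duration_ms / 1000
    for (j in which(ok)) {
      a <- ev[j] + r$latency_ms / 1000
      b <- a + dur_s
      idx <- (findInterval(a, spk, left.open = TRUE) + 1L):
        findInterval(b, spk, left.open = TRUE)
      if (length(idx) && idx[1] <= length(spk) && idx[1] <= idx[length(idx)]) {
        m[idx] <- m[idx] * f[j]
      }
      if (f[j] > 1) {
        n_extra <- stats::rpois(1, lambda * (f[j] - 1) * dur_s)
        if (n_extra > 0) extras <- c(extras, stats::runif(n_extra, a, b))
      }
    }
  }
  keep <- stats::runif(length(spk)) < pmin(m, 1)
  sort(c(spk[keep], extras))
}

SESSION_PRESETS <- c("monkeyC_TET", "monkeyD_TET", "monkeyC_PCT", "monkeyD_PCT")

preset_config <- function(preset) {
  switch(preset,
    monkeyC_TET = task_config("TET", 1.3, 2.3),
    monkeyD_TET = task_config("TET", 1.0, 2.0),
    # the Pavlovian variant uses fixed 1.0/2.0 s cue-to-reward delays
    monkeyC_PCT = task_config("PCT", 1.0, 2.0),
    monkeyD_PCT = task_config("PCT", 1.0, 2.0),
    stop("unknown preset: ", preset)
  )
}

# per-monkey electrophysiological and behavioral presets; rate/width
# moments follow the reported per-class means +/- SD, Weber fractions are
# calibrated so pooled correct rates land near the reported 89% (C) and
# 82% (D) under repeat-on-error scheduling (see the methods vignette)
preset_monkey <- function(preset) {
  if (grepl("C", preset)) {
    list(monkey = "C", weber = 0.13, p_motor = 46 / 114,
         tan_rate = c(5.94, 1.94), tan_width = c(905, 169),
         pan_rate = c(1.47, 1.91), pan_width = c(758, 80),
         p_cue_pause = 0.45, p_reward_pause = 0.25,
         cue_window = list(short = c(93, 309), long = c(93, 309)),
         reward_window = c(139, 369))
  } else {
    list(monkey = "D", weber = 0.20, p_motor = 34 / 86,
         tan_rate = c(4.82, 1.72), tan_width = c(1220, 194),
         pan_rate = c(1.83, 1.92), pan_width = c(656, 114),
         p_cue_pause = 0.27, p_reward_pause = 0.36,
         cue_window = list(short = c(127, 313), long = c(211, 418)),
         reward_window = c(194, 391))
  }
}

#' Generate a complete synthetic session
#'
#' Builds behavior, a unit population and spike trains for one of the four
#' session presets. Presets encode the per-monkey interval thresholds
#' (1.3/2.3 s vs 1.0/2.0 s; Pavlovian delays 1.0/2.0 s), the per-class
#' baseline-rate and spike-width distributions, and a mixture of
#' cue-pause-responsive, reward-responsive, rebound and unresponsive TANs
#' plus phasically activated PANs. Fully deterministic given `seed`.
#'
#' @param preset One of `"monkeyC_TET"`, `"monkeyD_TET"`, `"monkeyC_PCT"`,
#'   `"monkeyD_PCT"`.
#' @param n_units Number of units.
#' @param n_trials Number of trials.
#' @param seed Integer seed.
#' @param tan_fraction Fraction of units that are TANs.
#' @return A validated `tan_session`. Ground-truth response parameters are
#'   recorded in `metadata$responses_json`.
#' @export
generate_session <- function(preset = "monkeyC_TET", n_units = 30,
                             n_trials = 200, seed = 1, tan_fraction = 0.7) {
  if (!preset %in% SESSION_PRESETS) {
    stop("unknown preset: ", preset, " (expected one of ",
         paste(SESSION_PRESETS, collapse = ", "), ")")
  }
  cfg <- preset_config(preset)
  mk <- preset_monkey(preset)
  set.seed(seed)
  unit_seeds <- sample.int(2147483646L, n_units + 1L)

  bp <- behavior_params(
    n_trials = n_trials,
    mot_mean_short = cfg$short_threshold + 0.35,
    mot_mean_long = cfg$long_threshold + 0.35,
    weber_fraction = mk$weber,
    seed = unit_seeds[n_units + 1L]
  )
  trials <- generate_behavior(cfg, bp)

  set.seed(seed + 1L)
  n_tan <- round(tan_fraction * n_units)
  kinds <- c(rep("TAN", n_tan), rep("PAN", n_units - n_tan))
  units <- vector("list", n_units)
  spikes <- vector("list", n_units)
  truth <- vector("list", n_units)
  for (i in seq_len(n_units)) {
    uid <- sprintf("u%03d", i)
    kind <- kinds[i]
    if (kind == "TAN") {
      rate <- max(0.5, stats::rnorm(1, mk$tan_rate[1], mk$tan_rate[2]))
      width <- max(200, stats::rnorm(1, mk$tan_width[1], mk$tan_width[2]))
      resp <- list()
      if (stats::runif(1) < mk$p_cue_pause) {
        sel <- sample(c("short", "long", "both"), 1, prob = c(0.43, 0.43, 0.14))
        for (iv in if (sel == "both") c("short", "long") else sel) {
          w <- mk$cue_window[[iv]]
          resp <- c(resp, list(response_spec(
            "cue_on", latency_ms = w[1], duration_ms = diff(w),
            rate_factor = 0.25, interval = iv)))
        }
        if (stats::runif(1) < 0.12 / mk$p_cue_pause) {
          resp <- c(resp, list(response_spec(
            "cue_on", latency_ms = mk$cue_window$short[2],
            duration_ms = 150, rate_factor = 1.6)))
        }
      }
      if (stats::runif(1) < mk$p_reward_pause) {
        w <- mk$reward_window
        resp <- c(resp, list(response_spec(
          "reward", latency_ms = w[1], duration_ms = diff(w),
          rate_factor = 0.3)))
      }
    } else {
      rate <- max(0.2, stats::rnorm(1, mk$pan_rate[1], mk$pan_rate[2]))
      width <- max(200, stats::rnorm(1, mk$pan_width[1], mk$pan_width[2]))
      resp <- if (stats::runif(1) < 0.5) {
        list(response_spec("cue_on", latency_ms = 50, duration_ms = 300,
                           rate_factor = 3))
      } else list()
    }
    region <- if (stats::runif(1) < mk$p_motor) "motor" else "associative"
    ap <- if (region == "motor") stats::runif(1, -4, 0) else stats::runif(1, 0.1, 5)
    up <- unit_params(kind, baseline_rate = rate, spike_width = width,
                      responses = resp, seed = unit_seeds[i])
    st <- generate_spike_train(up, trials, cfg)
    units[[i]] <- data.frame(unit_id = uid, monkey = mk$monkey, region = region,
                             ap_position_mm = round(ap, 3),
                             baseline_rate = round(rate, 6),
                             spike_width = round(width, 1), label = kind,
                             stringsAsFactors = FALSE)
    spikes[[i]] <- if (length(st)) {
      data.frame(unit_id = uid, time_s = st, stringsAsFactors = FALSE)
    } else NULL
    truth[[i]] <- lapply(resp, function(r) {
      r[!vapply(r, is.null, logical(1))]
    })
    names(truth)[i] <- uid
  }

  meta <- list(
    preset = preset, seed = seed, n_trials = n_trials, n_units = n_units,
    responses_json = as.character(jsonlite::toJSON(truth, auto_unbox = TRUE,
                                                   digits = NA))
  )
  session(cfg, trials, do.call(rbind, units),
          do.call(rbind, spikes[!vapply(spikes, is.null, logical(1))]),
          metadata = meta)
}
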