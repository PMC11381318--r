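# shared fixtures and independent oracles

cfg_C <- task_config("TET", 1.3, 2.3)
cfg_D <- task_config("TET", 1.0, 2.0)

# tiny hand-built session: 2 units, 3 trials, hand-placed spikes
toy_session <- function() {
  trials <- data.frame(
    trial_index = 1:3,
    cue_side = c("left", "right", "left"),
    interval = c("short", "long", "short"),
    t_cue_on = c(1, 9, 17),
    t_bar_release = c(2.4, 11.5, 18.1),
    t_target_contact = c(2.8, 11.9, 18.5),
    t_reward = c(2.8, 11.9, NA),
    outcome = c("correct", "correct", "underestimation"),
    stringsAsFactors = FALSE
  )
  units <- data.frame(
    unit_id = c("tan1", "pan1"), monkey = "C",
    region = c("associative", "motor"), ap_position_mm = c(1.2, -2),
    baseline_rate = c(6, 1.5), spike_width = c(905, 758),
    label = c("TAN", "PAN"), stringsAsFactors = FALSE
  )
  spikes <- data.frame(
    unit_id = c(rep("tan1", 6), rep("pan1", 2)),
    time_s = c(0.6, 0.9, 1.05, 1.6, 9.2, 17.3, 1.2, 9.4),
    stringsAsFactors = FALSE
  )
  session(cfg_C, trials, units, spikes)
}

# trials with programmed outcomes at fixed event spacing (for run analyses)
trials_with_outcomes <- function(outcomes, interval = "short") {
  n <- length(outcomes)
  cue <- 1 + (seq_len(n) - 1) * 8
  correct <- outcomes == "correct"
  rel <- ifelse(outcomes == "excluded", NA, cue + 1.6)
  con <- ifelse(outcomes == "excluded", NA, cue + 2.0)
  data.frame(trial_index = seq_len(n), cue_side = "left",
             interval = interval, t_cue_on = cue,
             t_bar_release = rel, t_target_contact = con,
             t_reward = ifelse(correct, con, NA),
             outcome = outcomes, stringsAsFactors = FALSE)
}

# exact two-sided permutation p for the rank-sum statistic:
# P(|W - E| >= |w_obs - E|) over all assignments of the pooled values
exact_ranksum_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  W_obs <- sum(r[seq_len(n1)])
  E <- n1 * (length(pooled) + 1) / 2
  combs <- utils::combn(length(pooled), n1)
  W_all <- colSums(matrix(r[combs], nrow = n1))
  mean(abs(W_all - E) >= abs(W_obs - E) - 1e-9)
}
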