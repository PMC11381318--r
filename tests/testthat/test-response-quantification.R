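test_that("magnitude follows the percent-change formula", {
  # 3 events, window 500 ms, one spike per window = 2 Hz against 6 Hz baseline
  ev <- c(10, 20, 30)
  times <- c(10.1, 20.1, 30.1)
  expect_equal(response_magnitude(times, ev, c(0, 500), 6), -200 / 3)
  expect_equal(response_magnitude(times, ev, c(0, 500), 2), 0)
  # fully silenced window
  expect_equal(response_magnitude(numeric(0), ev, c(0, 500), 6), -100)
  expect_error(response_magnitude(times, ev, c(0, 500), 0), "baseline_rate")
})

test_that("magnitude is invariant under uniform time translation", {
  set.seed(12)
  ev <- c(5, 15, 25)
  times <- sort(runif(60, 0, 30))
  m1 <- response_magnitude(times, ev, c(93, 309), 6)
  m2 <- response_magnitude(times + 1234.5, ev + 1234.5, c(93, 309), 6)
  expect_equal(m1, m2)
})

test_that("injected factors are recovered as (f-1)x100 percent", {
  tr <- trials_with_outcomes(rep("correct", 300))
  up <- unit_params("TAN", baseline_rate = 6, seed = 81, responses = list(
    response_spec("cue_on", 120, 180, 0.3)))
  st <- generate_spike_train(up, tr, cfg_C)
  base <- baseline_rate_estimate(st, tr$t_cue_on)
  mag <- response_magnitude(st, tr$t_cue_on, c(120, 300), base)
  expect_lt(abs(mag - (-70)), 5)
})

test_that("magnitude_table yields one row per unit and interval", {
  s <- generate_session("monkeyC_TET", n_units = 5, n_trials = 60, seed = 23)
  m <- magnitude_table(s, "cue_on")
  expect_equal(nrow(m), 2 * 5)
  expect_setequal(unique(m$interval), c("short", "long"))
  expect_true(all(m$n_trials >= 1))
  expect_equal(m$magnitude,
               100 * (m$window_rate - m$baseline_rate) / m$baseline_rate)
})

test_that("the rewarded-only filter removes nothing when all trials are correct", {
  tr <- trials_with_outcomes(rep("correct", 40),
                             interval = rep(c("short", "long"), 20))
  units <- data.frame(unit_id = "u1", monkey = "C", region = "motor",
                      ap_position_mm = NA_real_, baseline_rate = 6,
                      spike_width = 900, label = "TAN")
  up <- unit_params("TAN", baseline_rate = 6, seed = 3)
  st <- generate_spike_train(up, tr, cfg_C)
  s <- session(cfg_C, tr, units, data.frame(unit_id = "u1", time_s = st))
  m_all <- magnitude_table(s, "cue_on", rewarded_only = FALSE)
  m_rw <- magnitude_table(s, "cue_on", rewarded_only = TRUE)
  expect_equal(m_rw$n_trials, m_all$n_trials)
  expect_equal(m_rw$magnitude, m_all$magnitude)
})

test_that("an interval-selective pause separates the condition means", {
  tr <- trials_with_outcomes(rep("correct", 200),
                             interval = rep(c("short", "long"), 100))
  units <- do.call(rbind, lapply(1:4, function(i) {
    data.frame(unit_id = sprintf("u%d", i), monkey = "C", region = "motor",
               ap_position_mm = NA_real_, baseline_rate = 6,
               spike_width = 900, label = "TAN")
  }))
  spikes <- do.call(rbind, lapply(1:4, function(i) {
    up <- unit_params("TAN", baseline_rate = 6, seed = 60 + i, responses = list(
      response_spec("cue_on", 93, 216, 0.2, interval = "short")))
    data.frame(unit_id = sprintf("u%d", i),
               time_s = generate_spike_train(up, tr, cfg_C))
  }))
  s <- session(cfg_C, tr, units, spikes)
  m <- magnitude_table(s, "cue_on")
  expect_lt(mean(m$magnitude[m$interval == "short"]),
            mean(m$magnitude[m$interval == "long"]) - 30)
})

test_that("population curves aggregate unit PSTHs with SEM over units", {
  tr <- trials_with_outcomes(rep("correct", 150))
  up <- unit_params("TAN", baseline_rate = 6, seed = 91)
  st <- generate_spike_train(up, tr, cfg_C)
  units <- do.call(rbind, lapply(c("a", "b"), function(id) {
    data.frame(unit_id = id, monkey = "C", region = "motor",
               ap_position_mm = NA_real_, baseline_rate = 6,
               spike_width = 900, label = "TAN")
  }))
  spikes <- rbind(data.frame(unit_id = "a", time_s = st),
                  data.frame(unit_id = "b", time_s = st))
  s <- session(cfg_C, tr, units, spikes)
  pc <- population_curve(s, span_ms = c(-200, 600))
  # identical units: SEM identically zero
  expect_true(all(pc$sem == 0))
  # flat tonic firing: curve mean near the 6 Hz baseline
  expect_lt(abs(mean(pc$mean_rate) - 6), 0.5)
  expect_equal(nrow(pc), 80)
  expect_error(population_curve(s, unit_ids = character(0)), "empty unit set")
})

test_that("Gaussian smoothing approximately preserves the curve mass", {
  tr <- trials_with_outcomes(rep("correct", 80))
  up <- unit_params("TAN", baseline_rate = 6, seed = 95, responses = list(
    response_spec("cue_on", 100, 200, 0.2)))
  st <- generate_spike_train(up, tr, cfg_C)
  units <- data.frame(unit_id = "a", monkey = "C", region = "motor",
                      ap_position_mm = NA_real_, baseline_rate = 6,
                      spike_width = 900, label = "TAN")
  s <- session(cfg_C, tr, units, data.frame(unit_id = "a", time_s = st))
  raw <- population_curve(s, span_ms = c(-500, 1500), sigma_bins = 0)
  sm <- population_curve(s, span_ms = c(-500, 1500), sigma_bins = 5)
  # away from the edges the normalized kernel conserves mass
  inner <- 30:170
  expect_lt(abs(sum(sm$mean_rate[inner]) / sum(raw$mean_rate[inner]) - 1), 0.01)
  # smoothing reduces roughness
  expect_lt(sum(diff(sm$mean_rate)^2), sum(diff(raw$mean_rate)^2))
})
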