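test_that("chi-square equals its closed form and the stats oracle", {
  set.seed(9)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 20) + 1, 2)
    a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
    r <- chi2_2x2(a, b, c, d)
    closed <- sum(tab) * (a * d - b * c)^2 /
      prod(rowSums(tab), colSums(tab))
    expect_equal(r$chi2, closed)
    oracle <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_equal(r$chi2, unname(oracle$statistic))
    expect_equal(r$p, unname(oracle$p.value))
    # simultaneous row/column swap leaves the statistic unchanged
    expect_equal(chi2_2x2(d, c, b, a)$chi2, r$chi2)
  }
  expect_equal(chi2_2x2(10, 10, 20, 20)$chi2, 0)
  expect_error(chi2_2x2(0, 0, 5, 5), "zero margin")
  expect_error(chi2_2x2(-1, 2, 3, 4), "nonnegative")
})

test_that("rank_compare matches the base-R Wilcoxon implementations", {
  set.seed(14)
  for (i in 1:20) {
    x <- round(rnorm(12, 0, 2), 1)  # rounding induces ties
    y <- round(rnorm(15, 0.5, 2), 1)
    r <- rank_compare(x, y)
    w <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                             correct = TRUE))
    expect_equal(r$p, w$p.value, tolerance = 1e-10)

    xp <- round(rnorm(12, 0, 2), 1)
    rp <- rank_compare(x, xp, paired = TRUE)
    wp <- suppressWarnings(stats::wilcox.test(x, xp, paired = TRUE,
                                              exact = FALSE, correct = TRUE))
    expect_equal(rp$p, wp$p.value, tolerance = 1e-10)
  }
})

test_that("rank_compare is symmetric, handles identity, and has power", {
  x <- c(1, 2, 3, 4.5)
  r <- rank_compare(x, x, paired = TRUE)
  expect_equal(r$z, 0)
  expect_equal(r$p, 1)

  set.seed(2)
  a <- rnorm(30); b <- rnorm(30, 1)
  r1 <- rank_compare(a, b); r2 <- rank_compare(b, a)
  expect_equal(r1$p, r2$p)
  expect_equal(r1$z, -r2$z)

  big_a <- rnorm(100); big_b <- rnorm(100, 1)  # shift of one SD
  expect_lt(rank_compare(big_a, big_b)$p, 0.001)
})

test_that("MOT trend returns slope, intercept and Spearman rho", {
  mots <- c(1.2, 1.4, 1.6, 1.8, 2.0)
  r <- mot_trend(c(-10, -20, -30, -40, -50), mots)
  expect_equal(r$rho, -1)
  expect_equal(r$slope, -50, tolerance = 1e-9)

  up <- mot_trend(c(-50, -40, -30, -20, -10), mots)
  expect_equal(up$rho, 1)

  flat <- mot_trend(rep(-20, 5), mots)
  expect_equal(flat$slope, 0)
  expect_equal(flat$rho, 0)

  expect_error(mot_trend(c(1, 2, 3), rep(1.5, 3)), "constant MOTs")
  expect_error(mot_trend(1:2, c(1.2, 1.4)), "at least 3")
})

test_that("the generator's programmed MOT coupling is recovered", {
  tr <- trials_with_outcomes(rep("correct", 500))
  # spread MOTs over a realistic range
  set.seed(77)
  mots <- runif(500, 1.3, 3.3)
  tr$t_bar_release <- tr$t_cue_on + mots
  tr$t_target_contact <- tr$t_bar_release + 0.4
  tr$t_reward <- tr$t_target_contact
  slope_true <- -20  # percent per second, deepening with later movements
  up <- unit_params("TAN", baseline_rate = 12, seed = 78, responses = list(
    response_spec("cue_on", 100, 400, 0.5, mot_coupling_slope = slope_true)))
  st <- generate_spike_train(up, tr, cfg_C)
  base <- baseline_rate_estimate(st, tr$t_cue_on)
  cnt <- aligned_counts(st, tr$t_cue_on, c(100, 500))
  mags <- 100 * (cnt / 0.4 - base) / base
  r <- mot_trend(mags, mots)
  expect_lt(abs(r$slope - slope_true), 0.2 * abs(slope_true))
  expect_lt(r$p, 0.01)
})

test_that("MOT bins tile from zero, half-open, empty bins omitted", {
  m <- c(-10, -20, -30, -40)
  b <- mot_binned_magnitudes(m, c(1.4, 1.5, 1.6, 2.6))
  expect_equal(b$bin_start_s, c(1.0, 1.5, 2.5))
  # MOT exactly 1.5 belongs to [1.5, 2.0)
  expect_equal(b$n, c(1, 2, 1))
  expect_equal(b$mean[2], -25)

  one <- mot_binned_magnitudes(m, c(1.1, 1.2, 1.3, 1.4))
  expect_equal(nrow(one), 1)
  expect_equal(one$n, 4)

  # bin means of an exact linear relation are linear in bin centers
  mots <- seq(0.05, 2.95, by = 0.1)
  lin <- mot_binned_magnitudes(5 - 30 * mots, mots)
  centers <- lin$bin_start_s + 0.25
  fit <- stats::lm(lin$mean ~ centers)
  expect_equal(unname(coef(fit)[2]), -30, tolerance = 1e-9)
})

test_that("correct runs are maximal, chronological, pooled over intervals", {
  o <- c(rep("correct", 5), "underestimation")
  expect_equal(find_correct_runs(trials_with_outcomes(o))$start_index, 1)
  expect_equal(find_correct_runs(trials_with_outcomes(o))$end_index, 5)

  # 45 trials correct exactly on 7-14 and 25-34
  o45 <- rep("underestimation", 45)
  o45[c(7:14, 25:34)] <- "correct"
  runs <- find_correct_runs(trials_with_outcomes(o45))
  expect_equal(runs$start_index, c(7, 25))
  expect_equal(runs$end_index, c(14, 34))
  expect_equal(runs$length, c(8, 10))

  expect_equal(nrow(find_correct_runs(trials_with_outcomes(rep("correct", 4)))), 0)
})

test_that("sequence trends recover an exact within-run line", {
  tr <- trials_with_outcomes(c(rep("correct", 5), "underestimation"))
  runs <- find_correct_runs(tr)
  tm <- data.frame(unit_id = "u1", trial_index = 1:5,
                   magnitude = c(-10, -20, -30, -40, -50))
  r <- sequence_trend(tm, runs)
  expect_equal(r$slope, -10, tolerance = 1e-9)
  expect_equal(r$rho, -1)
  expect_equal(r$positions$mean_magnitude, c(-10, -20, -30, -40, -50))

  flat <- sequence_trend(data.frame(unit_id = "u1", trial_index = 1:5,
                                    magnitude = rep(-20, 5)), runs)
  expect_equal(flat$slope, 0)
  expect_null(sequence_trend(tm, runs[0, ]))
})

test_that("region contrast tests frequencies and magnitudes", {
  resp <- data.frame(
    unit_id = sprintf("u%02d", 1:20),
    region = rep(c("associative", "motor"), each = 10),
    responsive = rep(c(TRUE, FALSE), 10))
  set.seed(4)
  mags <- data.frame(
    unit_id = rep(resp$unit_id, 2),
    region = rep(resp$region, 2),
    interval = rep(c("short", "long"), each = 20),
    magnitude = rnorm(40, -20, 5))
  rc <- region_contrast(mags, resp)
  expect_s3_class(rc$frequency, "contingency_result")
  expect_named(rc$magnitude, c("short", "long"))
  # identical region populations: frequency table is exactly balanced
  expect_equal(rc$frequency$chi2, 0)
  # identical magnitude samples give p = 1
  mags2 <- mags
  mags2$magnitude <- rep(rnorm(10, -20, 5), 4)
  rc2 <- region_contrast(mags2, resp)
  expect_equal(rc2$magnitude$short$p, 1)
  expect_error(region_contrast(mags, resp[resp$region == "motor", ]),
               "both regions")
})
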