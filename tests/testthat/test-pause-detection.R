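test_that("aligned counts are half-open and additive over adjacent windows", {
  ev <- c(10, 20)
  times <- c(10.05, 10.1, 10.2, 20.15)
  # spike exactly at the window end is not counted, at the start it is
  expect_equal(aligned_counts(times, ev, c(0, 100)), c(1, 0))
  expect_equal(aligned_counts(times, ev, c(100, 200)), c(1, 1))
  expect_equal(aligned_counts(10.1, 10, c(100, 200)), 1)   # at window start
  expect_equal(aligned_counts(10.2, 10, c(100, 200)), 0)   # at window end
  expect_error(aligned_counts(times, numeric(0), c(0, 100)), "empty event")

  set.seed(55)
  rtimes <- sort(runif(400, 0, 30))
  for (w in list(c(0, 50), c(50, 130), c(-200, 0))) {
    u <- c(w[1], w[1] + diff(w) / 2, w[2])
    expect_equal(
      aligned_counts(rtimes, ev, c(u[1], u[2])) +
        aligned_counts(rtimes, ev, c(u[2], u[3])),
      aligned_counts(rtimes, ev, w))
  }
})

test_that("stepwise test handles degenerate and extreme inputs", {
  same <- stepwise_test(rep(3, 20), rep(3, 20), 0.1, 0.1)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  expect_false(same$significant)

  sep <- stepwise_test(rep(3, 40), rep(0, 40), 0.5, 0.1)
  expect_true(sep$significant)
  expect_equal(sep$direction, "decrease")

  up <- stepwise_test(rep(1, 40), rep(9, 40), 0.1, 0.1)
  expect_equal(up$direction, "increase")
})

test_that("stepwise test is invariant under common rescaling of rates", {
  set.seed(7)
  a <- rpois(30, 3); b <- rpois(30, 2)
  r1 <- stepwise_test(a, b, 0.1, 0.1)
  r2 <- stepwise_test(a, b, 0.5, 0.5)
  expect_equal(r1$statistic, r2$statistic)
  expect_equal(r1$p, r2$p)
})

test_that("normal-approximation p matches exact enumeration on small groups", {
  # every achievable rank configuration for 5..8 observations per group
  for (n1 in 5:8) for (n2 in n1:8) {
    N <- n1 + n2
    combs <- utils::combn(N, n1)
    W_all <- colSums(matrix((1:N)[combs], nrow = n1))
    E <- n1 * (N + 1) / 2
    worst <- 0
    for (w in unique(W_all)) {
      p_exact <- mean(abs(W_all - E) >= abs(w - E) - 1e-9)
      x <- (1:N)[combs[, match(w, W_all)]]
      y <- setdiff(1:N, x)
      p_norm <- rank_compare(x, y)$p
      worst <- max(worst, abs(p_norm - p_exact))
    }
    expect_lt(worst, 0.02)
  }
  # tied count data against the permutation oracle: heavy ties at small
  # sample sizes limit the normal approximation to about one decimal
  set.seed(3)
  for (i in 1:10) {
    x <- rpois(9, 2)
    y <- rpois(9, 3)
    expect_lt(abs(rank_compare(x, y)$p - exact_ranksum_p(x, y)), 0.1)
  }
})

test_that("runs shorter than min_run are not reported", {
  expect_null(tanlab:::first_long_run(c(F, T, T, T, T, F, F), 5))
  expect_equal(tanlab:::first_long_run(c(F, T, T, T, T, T, F), 5), c(2L, 6L))
  # first qualifying run wins, and it is maximal
  expect_equal(tanlab:::first_long_run(rep(c(F, T), c(3, 8)), 5), c(4L, 11L))
})

test_that("a strong injected pause is localized to about one window width", {
  tr <- trials_with_outcomes(rep("correct", 60))
  up <- unit_params("TAN", baseline_rate = 6, seed = 71, responses = list(
    response_spec("cue_on", 120, 180, 0.1)))
  st <- generate_spike_train(up, tr, cfg_C)
  sc <- pause_scan(st, tr$t_cue_on, tr$t_cue_on, scan_config())
  expect_equal(sc$direction, "decrease")
  expect_true(abs(sc$pause_onset_ms - 120) <= 100)
  expect_true(abs(sc$pause_offset_ms - 300) <= 100)
  expect_gte(sc$pause_offset_ms, sc$pause_onset_ms)
  expect_true(sc$pause_onset_ms %in% sc$steps$start_ms)
  # the onset run is indeed min_run long in the step flags
  i0 <- match(sc$pause_onset_ms, sc$steps$start_ms)
  expect_true(all(sc$steps$sig_decrease[i0:(i0 + 4)]))
})

test_that("detection power falls with rate factor and rises with trials", {
  power_at <- function(f, n, seed) {
    tr <- trials_with_outcomes(rep("correct", n))
    hits <- vapply(1:8, function(i) {
      up <- unit_params("TAN", baseline_rate = 6, seed = seed + i,
                        responses = list(response_spec("cue_on", 120, 180, f)))
      st <- generate_spike_train(up, tr, cfg_C)
      sc <- pause_scan(st, tr$t_cue_on, tr$t_cue_on, scan_config())
      !is.na(sc$pause_onset_ms)
    }, logical(1))
    mean(hits)
  }
  expect_gte(power_at(0.1, 60, 100), power_at(0.8, 60, 200))
  expect_gte(power_at(0.3, 120, 300), power_at(0.3, 15, 400))
})

test_that("scan errors when the span holds fewer than min_run steps", {
  tr <- trials_with_outcomes(rep("correct", 10))
  up <- unit_params("TAN", baseline_rate = 6, seed = 5)
  st <- generate_spike_train(up, tr, cfg_C)
  expect_error(
    pause_scan(st, tr$t_cue_on, tr$t_cue_on,
               scan_config(scan_span_ms = c(0, 130))),
    "fewer than min_run")
})

test_that("quantification windows derive from onsets and offsets", {
  w <- derive_quant_window(c(100, 140, 180), c(300, 340, 380), "mean")
  expect_equal(c(w$start_ms, w$end_ms), c(140, 340))
  expect_equal(w$provenance, "derived")

  w1 <- derive_quant_window(150, 320)
  expect_equal(c(w1$start_ms, w1$end_ms), c(150, 320))

  wc <- derive_quant_window(seq(80, 180, 10), seq(280, 380, 10),
                            "central_coverage", coverage = 0.8)
  expect_equal(c(wc$start_ms, wc$end_ms), c(90, 370))
  expect_error(derive_quant_window(numeric(0), numeric(0)), "at least one")
})

test_that("preset quantification windows match the per-monkey tables", {
  expect_equal(unlist(quant_window_preset("C", "cue_on", "short")[1:2],
                      use.names = FALSE), c(93, 309))
  expect_equal(unlist(quant_window_preset("C", "cue_on", "long")[1:2],
                      use.names = FALSE), c(93, 309))
  expect_equal(unlist(quant_window_preset("D", "cue_on", "short")[1:2],
                      use.names = FALSE), c(127, 313))
  expect_equal(unlist(quant_window_preset("D", "cue_on", "long")[1:2],
                      use.names = FALSE), c(211, 418))
  expect_equal(unlist(quant_window_preset("C", "reward", "short")[1:2],
                      use.names = FALSE), c(139, 369))
  expect_equal(unlist(quant_window_preset("D", "reward", "long")[1:2],
                      use.names = FALSE), c(194, 391))
  expect_equal(quant_window_preset("C", "cue_on", "short")$provenance, "preset")
})
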