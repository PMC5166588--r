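test_that("LC-CUSUM recursion matches the frozen hand-derived examples", {
  sch <- fig4_learning()

  empty <- run_lc_cusum(integer(0), sch)
  expect_identical(nrow(empty), 0L)
  expect_true(is.na(signal_index(empty)))

  # 30 straight successes: 21 * s = 4.605 < h = 4.723 <= 22 * s = 4.824
  tr <- run_lc_cusum(rep(0, 30), sch)
  expect_identical(signal_index(tr), 22L)
  expect_identical(nrow(tr), 22L)          # trace ends at the signal
  expect_true(all(tr$score <= 0))          # plotted downwards
  expect_equal(tr$score[1], -sch$s)
  expect_true(tr$signal[22] && !any(tr$signal[-22]))

  # an initial failure is absorbed by the zero holding barrier
  tr2 <- run_lc_cusum(c(1, rep(0, 22)), sch)
  expect_equal(tr2$score[1], 0)
  expect_identical(signal_index(tr2), 23L)
  expect_gte(attr(tr2, "barrier_hits"), 1L)
})

test_that("monitoring CUSUM recursion matches the frozen examples", {
  sch <- fig4_monitoring()

  # all successes: the barrier pins the score at zero, no alarm
  tr <- run_cusum(rep(0, 50), sch)
  expect_true(all(tr$score == 0))
  expect_true(is.na(alarm_index(tr)))

  # 5 * (1 - s) = 4.319 < h = 4.853 <= 6 * (1 - s) = 5.183
  tr6 <- run_cusum(rep(1, 10), sch)
  expect_identical(alarm_index(tr6), 6L)
  expect_identical(nrow(tr6), 6L)
  expect_true(all(tr6$score >= 0))

  tr7 <- run_cusum(c(0, rep(1, 10)), sch)
  expect_identical(alarm_index(tr7), 7L)
})

test_that("phase and domain errors are raised", {
  expect_error(run_lc_cusum(c(0, 1), fig4_monitoring()), "learning")
  expect_error(run_cusum(c(0, 1), fig4_learning()), "monitoring")
  expect_error(run_cusum(c(0, 2), fig4_monitoring()), "binary")
  expect_error(run_lc_cusum(c(0, 1), list(s = 0.1)), "monitoring_scheme")
})

test_that("signal indices agree with the raw log-likelihood-ratio oracle", {
  set.seed(42)
  lrn <- derive_scheme(0.6, 0.1, phase = "learning")   # signals quickly
  mon <- fig4_monitoring()
  for (rep in 1:200) {
    y <- rbinom(sample(1:30, 1), 1, runif(1, 0.05, 0.8))
    expect_identical(signal_index(run_lc_cusum(y, lrn)),
                     llr_signal_oracle(y, 0.6, 0.1, phase = "learning"))
    expect_identical(alarm_index(run_cusum(y, mon)),
                     llr_signal_oracle(y, 0.105, 0.172,
                                       phase = "monitoring"))
  }
})

test_that("two-phase run chains the charts with a fresh monitoring start", {
  lrn <- fig4_learning(); mon <- fig4_monitoring()

  tr <- run_two_phase(rep(0, 114), lrn, mon)
  expect_identical(signal_index(tr), 22L)
  expect_true(is.na(alarm_index(tr)))
  expect_identical(nrow(tr), 114L)
  expect_identical(unique(tr$phase[1:22]), "learning")
  expect_identical(unique(tr$phase[23:114]), "monitoring")
  # the monitoring chart restarts from zero and stays there on successes
  expect_true(all(tr$score[23:114] == 0))
  # sign convention: learning scores <= 0, monitoring scores >= 0
  expect_true(all(tr$score[tr$phase == "learning"] <= 0))
  expect_true(all(tr$score[tr$phase == "monitoring"] >= 0))

  # constant failures pin the learning score at the barrier forever
  bad <- run_two_phase(rep(1, 60), lrn, mon)
  expect_true(is.na(signal_index(bad)))
  expect_false("monitoring" %in% bad$phase)
  expect_true(all(bad$score == 0))

  # deterioration after proficiency raises a monitoring alarm
  mixed <- run_two_phase(c(rep(0, 22), rep(1, 10)), lrn, mon)
  expect_identical(signal_index(mixed), 22L)
  expect_identical(alarm_index(mixed), 28L)  # 6 failures after the restart
})

test_that("trace CSV export is tidy and re-readable", {
  tr <- run_two_phase(c(rep(0, 25), 1, 1), fig4_learning(),
                      fig4_monitoring())
  f <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, f)
  back <- read.csv(f)
  expect_identical(names(back), c("case_index", "phase", "score", "signal"))
  expect_identical(nrow(back), nrow(tr))
  expect_equal(back$score, tr$score, tolerance = 1e-9)
})

test_that("Monte Carlo signal times are reproducible and hit the corners", {
  lrn <- fig4_learning(); mon <- fig4_monitoring()

  # perfect performance: the learning chart signals at exactly ceil(h/s)
  mc0 <- signal_time_monte_carlo(lrn, true_rate = 0, horizon = 50,
                                 replicates = 64, seed = 3)
  expect_equal(mc0$signal_fraction, 1)
  expect_equal(mc0$mean_signal_time, ceiling(lrn$h / lrn$s))

  # ... and the monitoring chart never alarms
  mcm <- signal_time_monte_carlo(mon, true_rate = 0, horizon = 200,
                                 replicates = 64, seed = 3)
  expect_equal(mcm$signal_fraction, 0)

  a <- signal_time_monte_carlo(lrn, 0.172, horizon = 114,
                               replicates = 500, seed = 9)
  b <- signal_time_monte_carlo(lrn, 0.172, horizon = 114,
                               replicates = 500, seed = 9)
  expect_identical(a, b)
  expect_error(signal_time_monte_carlo(lrn, 1.5, 10, 10, 1), "probability")
})
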