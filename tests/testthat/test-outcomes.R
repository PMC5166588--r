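test_that("outcome summary reproduces the case-series rate arithmetic", {
  s <- toy_series(114, failure_at = c(3, 10, 22, 40, 49),
                  cure_failures = 6)
  sm <- summarize_outcomes(s, window = 49)
  expect_identical(sm$n, 114L)
  expect_identical(sm$events, 5L)
  expect_equal(round(100 * sm$overall_rate, 1), 4.4)
  expect_equal(round(100 * sm$first_window_rate, 1), 10.2)
  expect_equal(sm$after_window_rate, 0)
  expect_identical(sm$cure_n, 108L)
  expect_equal(round(100 * sm$cure_rate, 1), 94.7)

  # running rate is cumulative events over cumulative cases
  expect_equal(sm$running_rate[114], sm$overall_rate)
  expect_equal(sm$running_rate[3], 1 / 3)
  expect_true(all(diff(sm$cumulative_events) >= 0))

  z <- summarize_outcomes(toy_series(20), window = 5)
  expect_identical(z$events, 0L)
  expect_true(all(z$running_rate == 0))

  expect_error(summarize_outcomes(s, window = 200), "window")
})

test_that("summary denominators use follow-up-complete cases only", {
  df <- data.frame(case_index = 1:10, outcome = c(1, rep(0, 9)),
                   followup_complete = c(rep(TRUE, 8), FALSE, FALSE))
  sm <- summarize_outcomes(case_series(df), window = 4)
  expect_identical(sm$n, 8L)
  expect_equal(sm$overall_rate, 1 / 8)
})

test_that("paired Ba comparison matches a hand-computed t statistic", {
  s <- case_series(data.frame(case_index = 1:3, outcome = 0,
                              pre_Ba = c(2, 3, 1),
                              post_Ba = c(-3, -2, -3), pre_TVL = 8,
                              post_TVL = 8))
  cmp <- compare_ba_prepost(s)
  d <- c(-5, -5, -4)
  expect_equal(cmp$n_pairs, 3)
  expect_equal(cmp$mean_pre, 2)
  expect_equal(cmp$mean_post, mean(c(-3, -2, -3)))
  expect_equal(cmp$mean_diff, mean(d))
  # closed form: t = dbar / (sd(d) / sqrt(n))
  expect_equal(cmp$t, mean(d) / (sd(d) / sqrt(3)))
  expect_equal(cmp$df, 2)
  expect_equal(cmp$p_value, 2 * pt(-abs(cmp$t), 2))

  same <- case_series(data.frame(case_index = 1:3, outcome = 0,
                                 pre_Ba = c(2, 3, 1),
                                 post_Ba = c(2, 3, 1)))
  cmp0 <- compare_ba_prepost(same)
  expect_equal(cmp0$mean_diff, 0)
  expect_equal(cmp0$t, 0)
  expect_equal(cmp0$p_value, 1)

  expect_error(compare_ba_prepost(toy_series(5)), ">= 2 cases")
})

test_that("generator parameter recovery: Ba means land near the targets", {
  s <- generate_cohort(cohort_spec(n = 2000, seed = 5))
  cmp <- compare_ba_prepost(s)
  expect_equal(cmp$mean_pre, 2.5, tolerance = 0.1)
  expect_equal(cmp$mean_post, -2.8, tolerance = 0.1)
  expect_lt(cmp$p_value, 1e-10)
})

test_that("a balanced symmetric design forces an odds ratio of exactly 1", {
  # 4-cell design, outcome independent of the +/-1 covariate, equal counts
  df <- data.frame(case_index = 1:40,
                   outcome = rep(c(0, 1), each = 20),
                   age = 50 + rep(c(-1, 1), 20),
                   followup_complete = TRUE)
  fit <- fit_healing_model(case_series(df), covariates = "age")
  expect_equal(fit$table$or[fit$table$term == "age"], 1, tolerance = 1e-8)
})

test_that("logistic coefficients match a brute-force likelihood grid", {
  df <- data.frame(case_index = 1:8,
                   outcome = c(0, 0, 1, 0, 1, 0, 1, 1),
                   age = c(1, 2, 3, 4, 5, 6, 7, 8),
                   followup_complete = TRUE)
  fit <- fit_healing_model(case_series(df), covariates = "age")
  ll_grid <- function(b0s, b1s) {
    g <- expand.grid(b0 = b0s, b1 = b1s)
    eta <- outer(df$age, g$b1) + matrix(g$b0, nrow = 8, ncol = nrow(g),
                                        byrow = TRUE)
    p <- plogis(eta)
    ll <- colSums(df$outcome * log(p) + (1 - df$outcome) * log(1 - p))
    g[which.max(ll), ]
  }
  coarse <- ll_grid(seq(-10, 5, by = 0.05), seq(-2, 2, by = 0.05))
  best <- ll_grid(seq(coarse$b0 - 0.06, coarse$b0 + 0.06, by = 0.001),
                  seq(coarse$b1 - 0.06, coarse$b1 + 0.06, by = 0.001))
  expect_equal(fit$table$estimate[2], best$b1, tolerance = 1.5e-3)
  expect_equal(fit$table$estimate[1], best$b0, tolerance = 1.5e-3)
  # invariants of the reported table
  expect_equal(fit$table$or, exp(fit$table$estimate))
  expect_true(all(fit$table$ci_lower < fit$table$or &
                    fit$table$or < fit$table$ci_upper))
  expect_true(fit$cox_snell_r2 >= 0 && fit$cox_snell_r2 < 1)
})

test_that("Cox & Snell R2 is zero for the intercept-only model", {
  s <- toy_series(50, failure_at = c(2, 9, 30))
  fit <- fit_healing_model(s, covariates = character(0))
  expect_equal(fit$cox_snell_r2, 0, tolerance = 1e-12)
  expect_equal(fit$loglik, fit$loglik_null)
})

test_that("degenerate model inputs raise explicit errors", {
  sep <- data.frame(case_index = 1:20,
                    outcome = rep(c(1, 0), each = 10),
                    age = c(rep(30, 10), rep(70, 10)),
                    followup_complete = TRUE)
  expect_error(fit_healing_model(case_series(sep), covariates = "age"),
               "separation|converge")
  const <- data.frame(case_index = 1:20, outcome = rep(c(0, 1), 10),
                      age = 50, followup_complete = TRUE)
  expect_error(fit_healing_model(case_series(const), covariates = "age"),
               "constant")
  allfail <- toy_series(20, failure_at = 1:20)
  expect_error(fit_healing_model(allfail, covariates = "case_index"),
               "constant")
  expect_error(fit_healing_model(toy_series(10), covariates = "height"),
               "unknown covariate")
})

test_that("fit export mirrors the coefficient table", {
  s <- generate_cohort(study_like_defaults(seed = 3))
  fit <- fit_healing_model(s)
  doc <- jsonlite::parse_json(write_fit(fit))
  expect_equal(doc$cox_snell_r2, fit$cox_snell_r2)
  expect_length(doc$coefficients, nrow(fit$table))
  f <- withr::local_tempfile(fileext = ".csv")
  write_fit(fit, f)
  back <- read.csv(f)
  expect_equal(back$or, fit$table$or, tolerance = 1e-9)
})
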