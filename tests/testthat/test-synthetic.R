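test_that("cohort specs validate their invariants", {
  expect_s3_class(study_like_defaults(), "cohort_spec")
  expect_error(cohort_spec(p_novice = 0.05, p_expert = 0.2), "p_expert")
  expect_error(cohort_spec(n = 50, tau = 60), "tau")
  expect_error(cohort_spec(learning_model = "logistic_decay", kappa = 0),
               "kappa")
  expect_error(cohort_spec(mechanism = list(case_index = 0.1)),
               "intercept")
  expect_error(cohort_spec(n = 0), "n must be")
})

test_that("generation is deterministic and byte-stable under a fixed seed", {
  spec <- study_like_defaults(seed = 17)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a, b)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_case_series(a, f1); write_case_series(b, f2)
  expect_identical(readLines(f1), readLines(f2))
  # different seeds give different outcome draws
  expect_false(identical(
    outcome_vector(generate_cohort(study_like_defaults(seed = 18))),
    outcome_vector(a)))
})

test_that("change-point mechanism confines failures to the novice window", {
  for (seed in 1:20) {
    s <- generate_cohort(cohort_spec(n = 114, p_novice = 0.102,
                                     p_expert = 0, tau = 49, seed = seed))
    expect_true(all(which(s$outcome == 1) <= 49))
  }
  none <- generate_cohort(cohort_spec(p_novice = 0, p_expert = 0,
                                      seed = 99))
  expect_equal(sum(none$outcome), 0)
  # expectation check: mean event count over seeds near 0.102 * 49 = 5.0
  ev <- vapply(1:150, function(sd)
    sum(generate_cohort(cohort_spec(seed = sd))$outcome), numeric(1))
  se <- sd(ev) / sqrt(length(ev))
  expect_lt(abs(mean(ev) - 0.102 * 49), 4 * se)
})

test_that("logistic-decay probabilities interpolate between the rates", {
  spec <- cohort_spec(n = 200, learning_model = "logistic_decay",
                      p_novice = 0.4, p_expert = 0.05, tau = 100,
                      kappa = 5, seed = 2)
  early <- vapply(1:40, function(sd)
    mean(generate_cohort(cohort_spec(n = 200, learning_model =
        "logistic_decay", p_novice = 0.4, p_expert = 0.05, tau = 100,
        kappa = 5, seed = sd))$outcome[1:50]), numeric(1))
  # far before the transition the rate sits at p_novice
  expect_lt(abs(mean(early) - 0.4), 0.03)
  late <- vapply(1:40, function(sd)
    mean(generate_cohort(cohort_spec(n = 200, learning_model =
        "logistic_decay", p_novice = 0.4, p_expert = 0.05, tau = 100,
        kappa = 5, seed = sd))$outcome[151:200]), numeric(1))
  expect_lt(abs(mean(late) - 0.05), 0.03)
  expect_s3_class(generate_cohort(spec), "case_series")
})

test_that("covariate draws recover the study-like descriptives", {
  means <- t(vapply(1:100, function(sd) {
    s <- generate_cohort(study_like_defaults(seed = sd))
    c(age = mean(s$age), bmi = mean(s$bmi), parity = mean(s$parity))
  }, numeric(3)))
  # 3-standard-error bands for the mean of 100 seeds x 114 cases
  expect_lt(abs(mean(means[, "age"]) - 65.8), 3 * 7.0 / sqrt(100 * 114))
  expect_lt(abs(mean(means[, "bmi"]) - 25.1), 3 * 3.0 / sqrt(100 * 114))
  expect_lt(abs(mean(means[, "parity"]) - 4.0), 0.1)
  one <- generate_cohort(study_like_defaults(seed = 1))
  expect_true(all(one$age >= 30 & one$age <= 90))
  expect_true(all(one$bmi >= 15 & one$bmi <= 45))
  expect_true(all(one$parity >= 0))
  expect_true(all(one$operation_time >= 10 & one$operation_time <= 240))
})

test_that("direct logistic mechanism drives the outcome as specified", {
  spec <- cohort_spec(n = 4000, mechanism = list(intercept = 2,
                                                 case_index = log(0.96)),
                      seed = 8)
  s <- generate_cohort(spec)
  # late cases have near-zero risk; the underflow warning is expected
  fit <- suppressWarnings(fit_healing_model(s, covariates = "case_index"))
  expect_lt(abs(fit$table$estimate[2] - log(0.96)), 0.02)
  expect_error(generate_cohort(cohort_spec(
    mechanism = list(intercept = 0, height = 1))), "unknown")
})

test_that("faster learners reach the LC-CUSUM limit earlier", {
  lrn <- fig4_learning()
  sig_time <- function(p_expert, seed) {
    s <- generate_cohort(cohort_spec(n = 300, p_novice = 0.272,
                                     p_expert = p_expert, tau = 30,
                                     seed = seed))
    k <- signal_index(run_lc_cusum(outcome_vector(s), lrn))
    if (is.na(k)) 301L else k
  }
  slow <- vapply(1:40, function(sd) sig_time(0.05, sd), integer(1))
  fast <- vapply(1:40, function(sd) sig_time(0.00, sd), integer(1))
  expect_gt(median(slow), median(fast))
})
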