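#' Summarize healing-abnormality outcomes of a case series
#'
#' Computes the event count and overall rate among follow-up-complete cases,
#' the rate within the first `window` cases and after them, the running rate
#' (cumulative events / cumulative cases at each case index — the decreasing
#' curve that tracks the learning effect), and the anatomic-cure and
#' reoperation counts when postoperative POP-Q exams / flags are available.
#'
#' Denominators use the follow-up-complete cases only; enrolled cases without
#' follow-up contribute to no rate.
#'
#' @param series A [case_series()].
#' @param window Case count splitting the early and late experience
#'   (default 49).
#' @return An `outcome_summary`: list with `n`, `events`, `overall_rate`,
#'   `window`, `first_window_rate`, `after_window_rate`, `running_rate`
#'   (vector, one value per case), `cure_n`, `cure_rate` (NA when no
#'   postoperative exams), `reoperation_n`.
#' @examples
#' s <- case_series(data.frame(case_index = 1:10,
#'                             outcome = c(1, 0, 0, 1, 0, 0, 0, 0, 0, 0)))
#' summarize_outcomes(s, window = 4)
#' @export
summarize_outcomes <- function(series, window = 49L) {
  stopifnot(inherits(series, "case_series"))
  fu <- series[series$followup_complete %in% TRUE, , drop = FALSE]
  n <- nrow(fu)
  if (!n) stop("summarize_outcomes: no follow-up-complete cases",
               call. = FALSE)
  window <- as.integer(window)
  if (window > n || window < 1)
    stop("summarize_outcomes: window must lie in 1..n (n = ", n, ")",
         call. = FALSE)
  y <- outcome_vector(fu <- case_series(fu))
  events <- sum(y)
  first <- y[seq_len(window)]
  after <- y[-seq_len(window)]
  cum_events <- cumsum(y)
  stage_post <- stage_anterior(fu$post_Aa, fu$post_Ba, fu$post_TVL)
  have_post <- !is.na(stage_post)
  cure_n <- if (any(have_post)) sum(stage_post[have_post] <= 1L) else NA_integer_
  structure(list(
    n = n, events = events, overall_rate = events / n,
    window = window,
    first_window_rate = mean(first),
    after_window_rate = if (length(after)) mean(after) else NA_real_,
    running_rate = cum_events / seq_len(n),
    cumulative_events = cum_events,
    cure_n = cure_n,
    cure_rate = if (any(have_post)) cure_n / sum(have_post) else NA_real_,
    reoperation_n = sum(fu$reoperation %in% TRUE)),
    class = "outcome_summary")
}

#' @export
print.outcome_summary <- function(x, ...) {
  cat(sprintf("Outcomes over %d follow-up-complete cases\n", x$n))
  cat(sprintf("  healing abnormalities: %d (%.1f%%)\n",
              x$events, 100 * x$overall_rate))
  cat(sprintf("  first %d cases: %.1f%%; thereafter: %.1f%%\n",
              x$window, 100 * x$first_window_rate,
              100 * x$after_window_rate))
  if (!is.na(x$cure_rate))
    cat(sprintf("  anatomic cure: %d (%.1f%%)\n", x$cure_n,
                100 * x$cure_rate))
  invisible(x)
}

#' Paired pre/post comparison of the Ba point
#'
#' Compares the anterior Ba point before surgery and at the 12-month exam
#' over cases with both measurements: means and standard deviations, the mean
#' difference, and a two-sided paired t-test.
#'
#' @param series A [case_series()] with `pre_Ba` and `post_Ba` for at least
#'   two cases.
#' @return List with `n_pairs`, `mean_pre`, `sd_pre`, `mean_post`, `sd_post`,
#'   `mean_diff` (post minus pre), `t`, `df`, `p_value`.
#' @export
compare_ba_prepost <- function(series) {
  stopifnot(inherits(series, "case_series"))
  ok <- !is.na(series$pre_Ba) & !is.na(series$post_Ba)
  if (sum(ok) < 2)
    stop("compare_ba_prepost: need >= 2 cases with both exams",
         call. = FALSE)
  pre <- series$pre_Ba[ok]; post <- series$post_Ba[ok]
  d <- post - pre
  if (all(d == d[1])) {
    # constant differences: t.test errors when sd is 0; report directly
    tt <- list(statistic = if (d[1] == 0) 0 else Inf * sign(d[1]),
               parameter = sum(ok) - 1,
               p.value = if (d[1] == 0) 1 else 0)
  } else {
    tt <- stats::t.test(post, pre, paired = TRUE)
  }
  list(n_pairs = sum(ok),
       mean_pre = mean(pre), sd_pre = stats::sd(pre),
       mean_post = mean(post), sd_post = stats::sd(post),
       mean_diff = mean(d),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}

#' Multivariable logistic model of healing-abnormality risk
#'
#' Fits a maximum-likelihood logistic regression of the binary
#' healing-abnormality outcome on the requested covariates (default: age,
#' BMI, surgeon case volume — the raw 1-based order of operation —, operation
#' time and parity, all adjusted for one another) and reports, per covariate,
#' the adjusted odds ratio `exp(b)`, its Wald 95% confidence interval
#' `exp(b +/- z * SE)` and Wald p-value, together with the model and null
#' log-likelihoods and Cox & Snell
#' `R^2 = 1 - exp((2/n) (LL_null - LL_model))`.
#'
#' @param series A [case_series()].
#' @param covariates Character vector of case-series column names
#'   (`case_index` is the surgeon case-volume covariate).
#' @param complete_followup_only Restrict to follow-up-complete cases
#'   (default `TRUE`, matching the rate denominators).
#' @param level Confidence level for the Wald intervals.
#' @return A `healing_fit`: list with `table` (data frame: term, estimate,
#'   se, or, ci_lower, ci_upper, p_value), `loglik`, `loglik_null`,
#'   `cox_snell_r2`, `n`, and the underlying `glm` object as `fit`.
#' @examples
#' spec <- study_like_defaults()
#' fit_healing_model(generate_cohort(spec))
#' @export
fit_healing_model <- function(series,
                              covariates = c("age", "bmi", "case_index",
                                             "operation_time", "parity"),
                              complete_followup_only = TRUE,
                              level = 0.95) {
  stopifnot(inherits(series, "case_series"))
  df <- as.data.frame(series)
  if (complete_followup_only)
    df <- df[df$followup_complete %in% TRUE, , drop = FALSE]
  miss <- setdiff(covariates, names(df))
  if (length(miss))
    stop("fit_healing_model: unknown covariate(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  keep <- stats::complete.cases(df[c("outcome", covariates)])
  df <- df[keep, , drop = FALSE]
  n <- nrow(df)
  if (n < length(covariates) + 1)
    stop("fit_healing_model: only ", n, " complete cases for ",
         length(covariates), " covariates", call. = FALSE)
  if (length(unique(df$outcome)) < 2)
    stop("fit_healing_model: outcome is constant; no model is estimable",
         call. = FALSE)
  for (cv in covariates)
    if (length(unique(df[[cv]])) < 2)
      stop("fit_healing_model: covariate '", cv, "' is constant",
           call. = FALSE)

  form <- if (length(covariates))
    stats::reformulate(covariates, response = "outcome")
  else outcome ~ 1
  fit <- stats::glm(form, family = stats::binomial(), data = df)
  if (!fit$converged)
    stop("fit_healing_model: IRLS did not converge", call. = FALSE)
  b <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  if (any(se[-1] > 1e3 * pmax(abs(b[-1]), 1)))
    stop("fit_healing_model: (quasi-)complete separation detected; ",
         "coefficients are not identifiable", call. = FALSE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  wald_p <- 2 * stats::pnorm(-abs(b / se))
  ll <- as.numeric(stats::logLik(fit))
  ll0 <- as.numeric(stats::logLik(stats::glm(outcome ~ 1,
                                             family = stats::binomial(),
                                             data = df)))
  tab <- data.frame(term = names(b), estimate = unname(b), se = unname(se),
                    or = exp(unname(b)),
                    ci_lower = exp(unname(b - z * se)),
                    ci_upper = exp(unname(b + z * se)),
                    p_value = unname(wald_p),
                    stringsAsFactors = FALSE)
  structure(list(table = tab, loglik = ll, loglik_null = ll0,
                 cox_snell_r2 = 1 - exp((2 / n) * (ll0 - ll)),
                 n = n, level = level, fit = fit),
            class = "healing_fit")
}

#' @export
print.healing_fit <- function(x, digits = 2, ...) {
  cat(sprintf("Logistic model of healing abnormality (n = %d)\n", x$n))
  tab <- x$table[-1, c("term", "or", "ci_lower", "ci_upper", "p_value")]
  tab[-1] <- lapply(tab[-1], round, digits)
  print(tab, row.names = FALSE)
  cat(sprintf("Cox & Snell R2: %.2f\n", x$cox_snell_r2))
  invisible(x)
}

#' Export a logistic fit as JSON or tidy CSV
#'
#' @param fit A [fit_healing_model()] result.
#' @param path Output path (`.json` or `.csv`); when `NULL`, returns the
#'   JSON string.
#' @export
write_fit <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "healing_fit"))
  if (!is.null(path) && grepl("\\.csv$", path)) {
    utils::write.csv(fit$table, path, row.names = FALSE)
    return(invisible(path))
  }
  x <- list(n = fit$n, level = fit$level, loglik = fit$loglik,
            loglik_null = fit$loglik_null, cox_snell_r2 = fit$cox_snell_r2,
            coefficients = fit$table)
  if (is.null(path)) return(jsonlite::toJSON(x, dataframe = "rows",
                                             auto_unbox = TRUE, digits = NA, na = "null"))
  jsonlite::write_json(x, path, dataframe = "rows", auto_unbox = TRUE, na = "null",
                       digits = NA)
  invisible(path)
}
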