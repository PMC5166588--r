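#' A prior study contributing to the benchmark failure rate
#'
#' Records one published cohort's healing-abnormality experience as an event
#' count out of `n` operations. Exactly one of `events` or `rate` must be
#' given; a rate is converted to events as `round(rate * n)` (a documented
#' reconstruction, since published reports often print only the percentage).
#'
#' @param label Study label.
#' @param n Cohort size (>= 1).
#' @param events Event count in `0..n`.
#' @param rate Event proportion in `[0, 1]` (alternative to `events`).
#' @return A `prior_study` (named list with `label`, `events`, `n`).
#' @examples
#' prior_study("Hinoul 2008", n = 76, rate = 0.105)
#' prior_study("Abdel-Fattah 2008", n = 48, events = 5)
#' @export
prior_study <- function(label, n, events = NULL, rate = NULL) {
  if (is.null(events) == is.null(rate))
    stop("prior_study: give exactly one of events or rate", call. = FALSE)
  n <- as.integer(n)
  if (is.na(n) || n < 1) stop("prior_study: n must be >= 1", call. = FALSE)
  if (is.null(events)) {
    if (rate < 0 || rate > 1)
      stop("prior_study: rate must lie in [0, 1]", call. = FALSE)
    events <- round(rate * n)
  }
  events <- as.integer(events)
  if (is.na(events) || events < 0 || events > n)
    stop("prior_study: events must lie in 0..n", call. = FALSE)
  structure(list(label = as.character(label), events = events, n = n),
            class = "prior_study")
}

#' Read prior studies from CSV
#'
#' Expects columns `label`, `n` and either `events` or `rate` (per row,
#' whichever is non-missing; `events` wins when both are present).
#'
#' @param path CSV path.
#' @return List of [prior_study()] objects.
#' @export
read_prior_studies <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(df)) stop("read_prior_studies: empty study table", call. = FALSE)
  if (!all(c("label", "n") %in% names(df)))
    stop("read_prior_studies: need columns label and n", call. = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    ev <- if ("events" %in% names(df)) df$events[i] else NA
    rt <- if ("rate" %in% names(df)) df$rate[i] else NA
    if (!is.na(ev)) prior_study(df$label[i], n = df$n[i], events = ev)
    else if (!is.na(rt)) prior_study(df$label[i], n = df$n[i], rate = rt)
    else stop("read_prior_studies: row ", i, " has neither events nor rate",
              call. = FALSE)
  })
}

#' Pool prior-study proportions into a benchmark rate
#'
#' Pools the event counts and denominators of the prior studies into a single
#' proportion and attaches its upper confidence bound — the two quantities
#' that parameterize the monitoring chart (acceptable rate = pooled estimate,
#' unacceptable rate = upper bound). Pooling is by simple event aggregation
#' (`sum(events) / sum(n)`); with two small homogeneous cohorts this
#' fixed-denominator pool is the natural default, and heterogeneity
#' weighting is deliberately out of scope.
#'
#' The upper bound is the upper limit of a two-sided confidence interval for
#' the pooled proportion:
#' `"exact"` — Clopper-Pearson (beta-quantile inversion of the binomial
#' tail), the default; `"wilson"` — Wilson score interval; `"normal"` —
#' Wald normal approximation.
#'
#' @param studies List of [prior_study()] objects (or a single one).
#' @param ci_method `"exact"`, `"wilson"` or `"normal"`.
#' @param level Two-sided confidence level (default 0.95).
#' @return A `pooled_benchmark`: list with `events`, `n`, `estimate`,
#'   `upper`, `ci_method`, `level`, `studies`.
#' @examples
#' pool_prior_rates(list(prior_study("a", 76, events = 8),
#'                       prior_study("b", 48, events = 5)))
#' @export
pool_prior_rates <- function(studies, ci_method = c("exact", "wilson",
                                                    "normal"),
                             level = 0.95) {
  ci_method <- match.arg(ci_method)
  if (inherits(studies, "prior_study")) studies <- list(studies)
  if (!length(studies))
    stop("pool_prior_rates: at least one study is required", call. = FALSE)
  if (!all(vapply(studies, inherits, TRUE, "prior_study")))
    stop("pool_prior_rates: studies must be prior_study objects",
         call. = FALSE)
  if (level <= 0 || level >= 1)
    stop("pool_prior_rates: level must lie in (0, 1)", call. = FALSE)
  x <- sum(vapply(studies, `[[`, 1L, "events"))
  n <- sum(vapply(studies, `[[`, 1L, "n"))
  est <- x / n
  upper <- binom_upper(x, n, level, ci_method)
  structure(list(events = x, n = n, estimate = est,
                 upper = min(upper, 1), ci_method = ci_method,
                 level = level, studies = studies),
            class = "pooled_benchmark")
}

# Upper limit of the two-sided CI for a binomial proportion.
binom_upper <- function(x, n, level, method) {
  a2 <- (1 - level) / 2
  switch(method,
    exact = if (x == n) 1 else stats::qbeta(1 - a2, x + 1, n - x),
    wilson = {
      z <- stats::qnorm(1 - a2)
      p <- x / n
      (p + z^2 / (2 * n) + z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) /
        (1 + z^2 / n)
    },
    normal = {
      z <- stats::qnorm(1 - a2)
      p <- x / n
      p + z * sqrt(p * (1 - p) / n)
    })
}

#' @export
print.pooled_benchmark <- function(x, ...) {
  cat(sprintf(paste0("Pooled benchmark: %d/%d events = %.1f%%; ",
                     "%s %.0f%% upper bound = %.1f%%\n"),
              x$events, x$n, 100 * x$estimate, x$ci_method, 100 * x$level,
              100 * x$upper))
  invisible(x)
}

#' Derive the (p0, p1) pairs for both chart phases from a benchmark
#'
#' Applies the phase-rate rule: for the monitoring CUSUM, the acceptable and
#' unacceptable failure rates are the pooled point estimate and its upper
#' confidence bound; for the learning LC-CUSUM they are the upper bound plus
#' `lc_offset` percentage points and the upper bound itself.
#'
#' @param benchmark A [pool_prior_rates()] result.
#' @param lc_offset Learning-phase offset in proportion units added to the
#'   upper bound (default 0.10, i.e. ten percentage points).
#' @return List with elements `learning` and `monitoring`, each `c(p0, p1)`.
#' @examples
#' b <- pool_prior_rates(list(prior_study("a", 76, events = 8),
#'                            prior_study("b", 48, events = 5)))
#' derive_phase_rates(b)
#' @export
derive_phase_rates <- function(benchmark, lc_offset = 0.10) {
  stopifnot(inherits(benchmark, "pooled_benchmark"))
  if (lc_offset < 0)
    stop("derive_phase_rates: lc_offset must be >= 0", call. = FALSE)
  up <- benchmark$upper
  if (up + lc_offset >= 1)
    stop("derive_phase_rates: upper bound + offset reaches 1; ",
         "no valid learning scheme exists", call. = FALSE)
  if (benchmark$estimate <= 0 || up >= 1)
    stop("derive_phase_rates: degenerate benchmark rates", call. = FALSE)
  list(learning = c(p0 = up + lc_offset, p1 = up),
       monitoring = c(p0 = benchmark$estimate, p1 = up))
}

#' Export a benchmark (and derived phase rates) as JSON
#'
#' @param benchmark A [pool_prior_rates()] result.
#' @param path Output path; when `NULL`, returns the JSON string.
#' @param lc_offset Passed to [derive_phase_rates()].
#' @export
write_benchmark_json <- function(benchmark, path = NULL, lc_offset = 0.10) {
  stopifnot(inherits(benchmark, "pooled_benchmark"))
  rates <- derive_phase_rates(benchmark, lc_offset)
  x <- list(events = benchmark$events, n = benchmark$n,
            estimate = benchmark$estimate, upper = benchmark$upper,
            ci_method = benchmark$ci_method, level = benchmark$level,
            phase_rates = lapply(rates, as.list))
  if (is.null(path)) return(jsonlite::toJSON(x, auto_unbox = TRUE, na = "null",
                                             digits = NA))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
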