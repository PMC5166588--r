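#' Run the learning-phase LC-CUSUM over a binary outcome sequence
#'
#' The LC-CUSUM tests H0 "performance is inadequate" against H1 "performance
#' is adequate" over consecutive cases. The normalized score starts at zero;
#' each success (outcome 0) subtracts the step `s`, each failure (outcome 1)
#' adds `1 - s`. A holding barrier at zero prevents the score from becoming
#' positive (truncation after each update). The chart signals — proficiency
#' is attained and the null rejected — at the first case whose update takes
#' the score to `-h` or below, and the trace ends there.
#'
#' Scores are reported on the plotting scale (non-positive values, the chart
#' drawn downwards).
#'
#' @param outcomes Binary 0/1 vector in case order (0 = success,
#'   1 = healing abnormality).
#' @param scheme A learning-phase [derive_scheme()] result.
#' @return A `monitoring_trace`: data frame with columns `case_index`,
#'   `phase`, `score`, `signal`, plus attributes `signal_index` (1-based case
#'   index of the proficiency signal, `NA` if never reached), `alarm_index`
#'   (always `NA` for a pure learning run) and `barrier_hits` (number of
#'   updates truncated at the zero barrier).
#' @examples
#' sch <- derive_scheme(0.272, 0.172, phase = "learning")
#' run_lc_cusum(rep(0, 30), sch)  # signals at case 22
#' @export
run_lc_cusum <- function(outcomes, scheme) {
  check_chart_inputs(outcomes, scheme, "learning")
  # in positive magnitude: each success steps +s towards the limit, each
  # failure steps -(1 - s) back, truncated at the zero holding barrier
  res <- chart_recursion(outcomes, step_fail = -(1 - scheme$s),
                         step_succ = scheme$s, h = scheme$h)
  new_trace(case_index = seq_along(res$score), phase = "learning",
            score = -res$score, signal = res$signal,
            signal_index = res$signal_index, alarm_index = NA_integer_,
            barrier_hits = res$barrier_hits)
}

#' Run the monitoring-phase CUSUM over a binary outcome sequence
#'
#' The monitoring CUSUM tests H0 "performance is adequate" against H1
#' "performance is inadequate". The score starts at zero; each failure adds
#' `1 - s`, each success subtracts `s`, with truncation at the zero holding
#' barrier from below (scores stay non-negative, the chart drawn upwards).
#' The chart alarms at the first case whose update takes the score to `+h`
#' or above.
#'
#' @param outcomes Binary 0/1 vector in case order.
#' @param scheme A monitoring-phase [derive_scheme()] result.
#' @return A `monitoring_trace` (see [run_lc_cusum()]); here `alarm_index`
#'   carries the signal and `signal_index` is `NA`.
#' @examples
#' sch <- derive_scheme(0.105, 0.172, phase = "monitoring")
#' run_cusum(rep(1, 10), sch)  # alarms at case 6
#' @export
run_cusum <- function(outcomes, scheme) {
  check_chart_inputs(outcomes, scheme, "monitoring")
  res <- chart_recursion(outcomes, step_fail = 1 - scheme$s,
                         step_succ = -scheme$s, h = scheme$h)
  new_trace(case_index = seq_along(res$score), phase = "monitoring",
            score = res$score, signal = res$signal,
            signal_index = NA_integer_, alarm_index = res$signal_index,
            barrier_hits = res$barrier_hits)
}

# Shared one-sided recursion in positive magnitude: per case the score moves
# by step_fail (outcome 1) or step_succ (outcome 0), is truncated at the zero
# holding barrier after the update, and signals when it reaches h. Exact hits
# count as signals (absolute tolerance 1e-12). The trace stops at the
# signalling case.
chart_recursion <- function(outcomes, step_fail, step_succ, h, tol = 1e-12) {
  n <- length(outcomes)
  score <- numeric(0)
  signal_index <- NA_integer_
  barrier_hits <- 0L
  x <- 0
  if (n) {
    score <- numeric(n)
    for (i in seq_len(n)) {
      x <- x + if (outcomes[i] == 1) step_fail else step_succ
      if (x < 0) {
        x <- 0
        barrier_hits <- barrier_hits + 1L
      }
      score[i] <- x
      if (x >= h - tol) {
        signal_index <- i
        score <- score[seq_len(i)]
        break
      }
    }
  }
  list(score = score, signal_index = signal_index,
       barrier_hits = barrier_hits,
       signal = seq_along(score) == ifelse(is.na(signal_index), 0L,
                                           signal_index))
}

check_chart_inputs <- function(outcomes, scheme, phase) {
  if (!inherits(scheme, "monitoring_scheme"))
    stop("expected a monitoring_scheme from derive_scheme()", call. = FALSE)
  if (scheme$phase != phase)
    stop("scheme phase is '", scheme$phase, "' but a ", phase,
         "-phase scheme is required", call. = FALSE)
  if (length(outcomes) && !all(outcomes %in% c(0, 1)))
    stop("outcomes must be a binary 0/1 sequence", call. = FALSE)
  invisible(TRUE)
}

new_trace <- function(case_index, phase, score, signal,
                      signal_index, alarm_index, barrier_hits) {
  df <- data.frame(case_index = as.integer(case_index),
                   phase = rep_len(phase, length(case_index)),
                   score = score, signal = signal,
                   stringsAsFactors = FALSE)
  structure(df, class = c("monitoring_trace", "data.frame"),
            signal_index = as.integer(signal_index),
            alarm_index = as.integer(alarm_index),
            barrier_hits = as.integer(barrier_hits))
}

#' @export
print.monitoring_trace <- function(x, ...) {
  si <- attr(x, "signal_index"); ai <- attr(x, "alarm_index")
  cat("Sequential monitoring trace over", nrow(x), "case(s)\n")
  cat("  proficiency signal:",
      if (is.na(si)) "not attained" else paste("case", si), "\n")
  if ("monitoring" %in% x$phase || !is.na(ai))
    cat("  monitoring alarm:  ",
        if (is.na(ai)) "none" else paste("case", ai), "\n")
  invisible(x)
}

#' Proficiency signal index of a trace
#' @param trace A `monitoring_trace`.
#' @return Integer case index, or `NA` if the chart never signalled.
#' @export
signal_index <- function(trace) attr(trace, "signal_index")

#' Monitoring alarm index of a trace
#' @param trace A `monitoring_trace`.
#' @return Integer case index, or `NA` if no alarm.
#' @export
alarm_index <- function(trace) attr(trace, "alarm_index")

#' Chain the learning LC-CUSUM into the monitoring CUSUM
#'
#' Runs the LC-CUSUM from case 1. If proficiency is signalled at case `k`,
#' the learning chart ends there and the monitoring CUSUM starts from score
#' zero at case `k + 1`, running over the remaining cases. If the LC-CUSUM
#' never signals, no monitoring phase occurs.
#'
#' @param outcomes Binary 0/1 vector in case order.
#' @param learning Learning-phase scheme ([derive_scheme()]).
#' @param monitoring Monitoring-phase scheme.
#' @return A combined `monitoring_trace` with per-case phase labels,
#'   `signal_index` (proficiency) and `alarm_index` (deterioration, if any).
#' @examples
#' lrn <- derive_scheme(0.272, 0.172, phase = "learning")
#' mon <- derive_scheme(0.105, 0.172, phase = "monitoring")
#' run_two_phase(rep(0, 114), lrn, mon)
#' @export
run_two_phase <- function(outcomes, learning, monitoring) {
  lc <- run_lc_cusum(outcomes, learning)
  k <- signal_index(lc)
  if (is.na(k) || k >= length(outcomes)) {
    attr(lc, "alarm_index") <- NA_integer_
    return(lc)
  }
  rest <- outcomes[(k + 1L):length(outcomes)]
  cu <- run_cusum(rest, monitoring)
  df <- rbind(as.data.frame(lc),
              within(as.data.frame(cu), case_index <- case_index + k))
  new_trace(case_index = df$case_index, phase = df$phase, score = df$score,
            signal = df$signal, signal_index = k,
            alarm_index = if (is.na(alarm_index(cu))) NA_integer_
                          else alarm_index(cu) + k,
            barrier_hits = attr(lc, "barrier_hits") + attr(cu, "barrier_hits"))
}

#' Export a trace as tidy CSV
#'
#' Writes one row per case: `case_index`, `phase`, `score`, `signal` — the
#' plotting interface for external charting tools.
#'
#' @param trace A `monitoring_trace`.
#' @param path Output CSV path.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "monitoring_trace"))
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Monte Carlo signal-time distribution of a chart
#'
#' Simulates i.i.d. Bernoulli(`true_rate`) failure sequences of length
#' `horizon`, runs the phase-appropriate chart on each, and summarizes when
#' (and how often) it signals — an operating-characteristic check for a
#' scheme before deploying it.
#'
#' @param scheme A [derive_scheme()] result (either phase).
#' @param true_rate True per-case failure probability, in (0, 1) or 0/1 for
#'   the degenerate corners.
#' @param horizon Number of cases per replicate.
#' @param replicates Number of simulated sequences.
#' @param seed Integer seed (reproducible).
#' @return List with `signal_fraction` (share of replicates signalling within
#'   the horizon), `mean_signal_time` and `signal_time_quantiles` (2.5%, 25%,
#'   50%, 75%, 97.5%) over signalling replicates (`NA` if none), and the
#'   call's parameters.
#' @export
signal_time_monte_carlo <- function(scheme, true_rate, horizon = 114L,
                                    replicates = 1000L, seed = 1L) {
  stopifnot(inherits(scheme, "monitoring_scheme"))
  if (!is.numeric(true_rate) || true_rate < 0 || true_rate > 1)
    stop("true_rate must be a probability in [0, 1]", call. = FALSE)
  if (replicates < 1 || horizon < 1)
    stop("horizon and replicates must be >= 1", call. = FALSE)
  s <- scheme$s; h <- scheme$h
  if (scheme$phase == "learning") {
    step_fail <- -(1 - s); step_succ <- s
  } else {
    step_fail <- 1 - s; step_succ <- -s
  }
  times <- with_seed(seed, {
    # replicate-vectorized recursion: one slot per replicate
    x <- numeric(replicates)
    tm <- rep(NA_integer_, replicates)
    alive <- rep(TRUE, replicates)
    for (i in seq_len(horizon)) {
      if (!any(alive)) break
      fails <- stats::rbinom(replicates, 1L, true_rate) == 1L
      x[alive] <- x[alive] + ifelse(fails[alive], step_fail, step_succ)
      x[alive & x < 0] <- 0
      hit <- alive & x >= h - 1e-12
      tm[hit] <- i
      alive <- alive & !hit
    }
    tm
  })
  signalled <- !is.na(times)
  list(signal_fraction = mean(signalled),
       mean_signal_time = if (any(signalled)) mean(times[signalled])
                          else NA_real_,
       signal_time_quantiles = if (any(signalled))
         stats::quantile(times[signalled], c(0.025, 0.25, 0.5, 0.75, 0.975))
       else NULL,
       true_rate = true_rate, horizon = as.integer(horizon),
       replicates = as.integer(replicates), seed = as.integer(seed),
       phase = scheme$phase)
}
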