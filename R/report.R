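#' Full sequential-proficiency analysis of a case series
#'
#' Orchestrates the whole pipeline on one case series: pools the prior-study
#' benchmark, derives the phase rates and both scheme constants, runs the
#' chained LC-CUSUM/CUSUM over the follow-up-complete outcome sequence, and
#' attaches the outcome summary and (when the covariates are present) the
#' adjusted logistic model.
#'
#' @param series A [case_series()].
#' @param studies Prior studies for the benchmark (list of [prior_study()]);
#'   default: the two anterior-mesh cohorts shipped with the package
#'   (8/76 and 5/48 events).
#' @param alpha,beta Error probabilities of both schemes.
#' @param lc_offset Learning-phase offset over the upper bound (proportion).
#' @param ci_method Benchmark CI method, see [pool_prior_rates()].
#' @param window Early-experience window for [summarize_outcomes()].
#' @param fit_model Fit the logistic model (skipped automatically when the
#'   covariates are absent or the outcome is constant).
#' @return An `analysis_report`: list with `benchmark`, `phase_rates`,
#'   `schemes` (learning and monitoring), `trace`, `proficiency_index`,
#'   `alarm_index`, `summary`, `fit` (or `NULL`), `provenance`.
#' @examples
#' rep <- analyze_case_series(generate_cohort(study_like_defaults()))
#' rep$proficiency_index
#' @export
analyze_case_series <- function(series, studies = shipped_prior_studies(),
                                alpha = 0.05, beta = 0.20,
                                lc_offset = 0.10,
                                ci_method = "exact",
                                window = 49L, fit_model = TRUE) {
  stopifnot(inherits(series, "case_series"))
  benchmark <- pool_prior_rates(studies, ci_method = ci_method)
  rates <- derive_phase_rates(benchmark, lc_offset)
  learning <- derive_scheme(rates$learning["p0"], rates$learning["p1"],
                            alpha, beta, phase = "learning")
  monitoring <- derive_scheme(rates$monitoring["p0"],
                              rates$monitoring["p1"],
                              alpha, beta, phase = "monitoring")
  y <- outcome_vector(series, complete_only = TRUE)
  trace <- run_two_phase(y, learning, monitoring)
  window <- min(as.integer(window), length(y))
  smry <- summarize_outcomes(series, window = window)
  fit <- NULL
  if (fit_model) {
    fit <- tryCatch(fit_healing_model(series), error = function(e) NULL)
  }
  structure(list(benchmark = benchmark, phase_rates = rates,
                 schemes = list(learning = learning,
                                monitoring = monitoring),
                 trace = trace,
                 proficiency_index = signal_index(trace),
                 alarm_index = alarm_index(trace),
                 summary = smry, fit = fit,
                 provenance = list(
                   n_cases = nrow(series),
                   n_followup = length(y),
                   package_version =
                     as.character(utils::packageVersion("lccusum")))),
            class = "analysis_report")
}

#' The two anterior-mesh prior cohorts shipped with the package
#'
#' Event counts reconstructed as `round(rate * n)` from the published
#' healing-abnormality rates (10.5% of 76 and 10.4% of 48 operations).
#'
#' @return List of two [prior_study()] objects.
#' @export
shipped_prior_studies <- function() {
  read_prior_studies(system.file("extdata", "prior_studies.csv",
                                 package = "lccusum", mustWork = TRUE))
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("== Sequential proficiency analysis ==\n")
  print(x$benchmark)
  print(x$schemes$learning)
  print(x$schemes$monitoring)
  cat(if (is.na(x$proficiency_index)) "Proficiency not attained\n"
      else sprintf("Proficiency attained at case %d\n",
                   x$proficiency_index))
  cat(if (is.na(x$alarm_index)) "No monitoring alarm\n"
      else sprintf("Monitoring alarm at case %d\n", x$alarm_index))
  print(x$summary)
  if (!is.null(x$fit)) print(x$fit)
  invisible(x)
}

#' Write an analysis report as JSON
#'
#' Serializes every component of an [analyze_case_series()] result into one
#' machine-readable document (the trace inlined as rows); re-running the
#' analysis on the same inputs reproduces the document bit-for-bit.
#'
#' @param report An `analysis_report`.
#' @param path Output path; when `NULL`, returns the JSON string.
#' @export
write_report <- function(report, path = NULL) {
  stopifnot(inherits(report, "analysis_report"))
  x <- list(
    benchmark = list(events = report$benchmark$events,
                     n = report$benchmark$n,
                     estimate = report$benchmark$estimate,
                     upper = report$benchmark$upper,
                     ci_method = report$benchmark$ci_method,
                     level = report$benchmark$level),
    phase_rates = lapply(report$phase_rates, as.list),
    schemes = lapply(report$schemes, function(s)
      s[c("phase", "p0", "p1", "alpha", "beta", "s", "h", "plot_sign")]),
    proficiency_index = report$proficiency_index,
    alarm_index = report$alarm_index,
    trace = as.data.frame(report$trace),
    summary = report$summary[c("n", "events", "overall_rate", "window",
                               "first_window_rate", "after_window_rate",
                               "cure_n", "cure_rate", "reoperation_n")],
    fit = if (!is.null(report$fit))
      list(n = report$fit$n, cox_snell_r2 = report$fit$cox_snell_r2,
           coefficients = report$fit$table),
    provenance = report$provenance)
  if (is.null(path))
    return(jsonlite::toJSON(x, dataframe = "rows", auto_unbox = TRUE,
                            digits = NA, null = "null", na = "null"))
  jsonlite::write_json(x, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' Structural check of a report document
#'
#' Validates a report JSON document against the shipped schema
#' (`inst/schema/analysis-report-schema.json`): required keys present and of
#' the expected JSON types. A lightweight structural validator, not a full
#' JSON-Schema engine.
#'
#' @param path Path to a report JSON file (or a JSON string).
#' @return `TRUE` invisibly; otherwise an error naming the first violation.
#' @export
validate_report_json <- function(path) {
  doc <- if (file.exists(path)) jsonlite::read_json(path)
         else jsonlite::parse_json(path)
  schema <- jsonlite::read_json(system.file("schema",
                                            "analysis-report-schema.json",
                                            package = "lccusum",
                                            mustWork = TRUE))
  check_node <- function(node, spec, where) {
    for (key in names(spec$required)) {
      if (!key %in% names(node))
        stop("report schema: missing '", key, "' at ", where, call. = FALSE)
      want <- spec$required[[key]]
      val <- node[[key]]
      is_jnull <- is.null(val) || (is.list(val) && !length(val))
      ok <- switch(as.character(want),
                   number = is.numeric(val) || is_jnull,
                   string = is.character(val),
                   object = is.list(val),
                   array = is.list(val),
                   TRUE)
      if (!ok)
        stop("report schema: '", key, "' at ", where, " should be ", want,
             call. = FALSE)
    }
  }
  check_node(doc, schema, "top level")
  check_node(doc$benchmark, schema$children$benchmark, "benchmark")
  for (ph in c("learning", "monitoring"))
    check_node(doc$schemes[[ph]], schema$children$scheme,
               paste0("schemes$", ph))
  invisible(TRUE)
}
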