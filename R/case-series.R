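#' Canonical column names of a case series
#'
#' A case series is stored as a data frame with one row per operated patient,
#' in order of operation. Canonical columns:
#' `case_index` (1-based order of operation, the surgeon case-volume
#' covariate), `outcome` (binary healing-abnormality flag, 1 = abnormality
#' within follow-up), `age` (years), `bmi` (kg/m^2), `parity` (count),
#' `operation_time` (minutes), `followup_complete` (logical), the optional
#' ancillary flags `reoperation`, `bladder_perforation`, `sui`, `frequency`,
#' and the POP-Q exams as prefixed columns `pre_Aa` ... `pre_PB` and
#' `post_Aa` ... `post_PB`.
#'
#' @keywords internal
#' @name case_series_columns
NULL

popq_fields <- c("Aa", "Ba", "C", "D", "Ap", "Bp", "TVL", "GH", "PB")

series_required_cols <- c("case_index", "outcome")
series_numeric_cols <- c("age", "bmi", "parity", "operation_time")
series_flag_cols <- c("followup_complete", "reoperation",
                      "bladder_perforation", "sui", "frequency")
series_popq_cols <- c(paste0("pre_", popq_fields), paste0("post_", popq_fields))
series_all_cols <- c(series_required_cols, series_numeric_cols,
                     series_flag_cols, series_popq_cols)

#' Construct a case series
#'
#' Validates and orders a data frame of consecutive operations into a
#' `case_series` object. Unknown columns are dropped; missing optional columns
#' are added as `NA` (absent, never imputed). When `followup_complete` is
#' absent it is derived from the presence of a postoperative `Ba` measurement.
#'
#' @param df Data frame with at least `case_index` and `outcome` columns
#'   (see [case_series_columns]).
#' @return A `case_series`: data frame sorted by `case_index` with the
#'   canonical columns.
#' @examples
#' case_series(data.frame(case_index = 1:3, outcome = c(0, 1, 0)))
#' @export
case_series <- function(df) {
  df <- as.data.frame(df)
  missing_req <- setdiff(series_required_cols, names(df))
  if (length(missing_req))
    stop("case_series: missing required column(s): ",
         paste(missing_req, collapse = ", "), call. = FALSE)
  for (col in setdiff(series_all_cols, names(df)))
    df[[col]] <- if (col %in% series_flag_cols) NA else NA_real_
  df <- df[series_all_cols]

  df$case_index <- as.integer(df$case_index)
  df$outcome <- suppressWarnings(as.numeric(df$outcome))
  for (col in c(series_numeric_cols, series_popq_cols))
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  for (col in series_flag_cols)
    df[[col]] <- as_flag(df[[col]])

  bad <- which(is.na(df$case_index) | df$case_index < 1L)
  if (length(bad))
    stop("case_series: invalid case_index at row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$case_index))
    stop("case_series: duplicate case_index value(s): ",
         paste(unique(df$case_index[duplicated(df$case_index)]),
               collapse = ", "), call. = FALSE)
  bad <- which(!(df$outcome %in% c(0, 1)))
  if (length(bad))
    stop("case_series: outcome must be 0 or 1; violated at row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  for (col in c("age", "bmi", "operation_time")) {
    bad <- which(!is.na(df[[col]]) & df[[col]] <= 0)
    if (length(bad))
      stop("case_series: ", col, " must be positive; violated at row(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.na(df$parity) & df$parity < 0)
  if (length(bad))
    stop("case_series: parity must be >= 0; violated at row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)

  if (all(is.na(df$followup_complete)))
    df$followup_complete <- !is.na(df$post_Ba)
  df <- df[order(df$case_index), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("case_series", "data.frame")
  df
}

as_flag <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(ifelse(is.na(x), NA, x != 0))
  x <- trimws(as.character(x))
  out <- rep(NA, length(x))
  out[x %in% c("1", "TRUE", "true", "yes")] <- TRUE
  out[x %in% c("0", "FALSE", "false", "no")] <- FALSE
  out
}

#' @export
print.case_series <- function(x, ...) {
  cat("Case series: ", nrow(x), " consecutive operations, ",
      sum(x$outcome), " healing abnormalities (",
      sum(x$followup_complete, na.rm = TRUE), " with complete follow-up)\n",
      sep = "")
  NextMethod()
}

#' Outcome vector of a case series
#'
#' @param series A [case_series()].
#' @param complete_only Restrict to follow-up-complete cases.
#' @return Integer 0/1 vector in case order.
#' @export
outcome_vector <- function(series, complete_only = FALSE) {
  stopifnot(inherits(series, "case_series"))
  if (complete_only) series <- series[series$followup_complete %in% TRUE, ]
  as.integer(series$outcome)
}

#' Default column mapping for the deposited dataset schema
#'
#' The deposited patient table uses terse column names (`"op ordinal"` for the
#' order of operation, `"erosion"` for the healing-abnormality flag, `"para"`
#' for parity, `"optime"` for operation time, and POP-Q columns prefixed `0`
#' for the preoperative and `1` for the 12-month exam, e.g. `"0Ba"`, `"1Ba"`).
#' This map translates those names to the canonical case-series columns; pass
#' a modified copy to [read_case_series()] to override.
#'
#' The `erosion` column is taken as the binary healing-abnormality outcome
#' (the clinical definition spans erosion, rejection, infection and exposure;
#' the deposited table exposes a single erosion flag, assumed equivalent).
#'
#' @return Named character vector: names are source CSV headers, values are
#'   canonical column names.
#' @export
default_schema_map <- function() {
  m <- c("op ordinal" = "case_index", "erosion" = "outcome", "age" = "age",
         "BMI" = "bmi", "para" = "parity", "optime" = "operation_time",
         "reop" = "reoperation", "bladder perfo" = "bladder_perforation",
         "SUI" = "sui", "frequency" = "frequency")
  c(m,
    stats::setNames(paste0("pre_", popq_fields), paste0("0", popq_fields)),
    stats::setNames(paste0("post_", popq_fields), paste0("1", popq_fields)))
}

#' Read a case series from CSV
#'
#' Reads a comma-separated table (header row, UTF-8) of consecutive
#' operations. Canonical column names are accepted as-is; other headers are
#' translated through `schema_map` (by default the deposited-dataset map of
#' [default_schema_map()]). Rows failing validation are reported with their
#' row numbers; missing optional fields are carried as `NA`.
#'
#' @param path CSV file path.
#' @param schema_map Named character vector mapping source headers to
#'   canonical names, or a path to a JSON file holding such a map.
#' @return A [case_series()] sorted by `case_index`.
#' @export
read_case_series <- function(path, schema_map = default_schema_map()) {
  if (!file.exists(path))
    stop("read_case_series: no such file: ", path, call. = FALSE)
  if (is.character(schema_map) && length(schema_map) == 1 &&
      file.exists(schema_map) && grepl("\\.json$", schema_map))
    schema_map <- unlist(jsonlite::read_json(schema_map))
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  hit <- names(df) %in% names(schema_map)
  names(df)[hit] <- unname(schema_map[names(df)[hit]])
  missing_req <- setdiff(series_required_cols, names(df))
  if (length(missing_req))
    stop("read_case_series: required column(s) absent after mapping: ",
         paste(missing_req, collapse = ", "), call. = FALSE)
  case_series(df)
}

#' Write a case series to CSV
#'
#' Writes the canonical columns; absent optional fields become empty cells so
#' that `read_case_series(write_case_series(s))` round-trips field-for-field.
#'
#' @param series A [case_series()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_case_series <- function(series, path) {
  stopifnot(inherits(series, "case_series"))
  out <- as.data.frame(series)
  for (col in series_flag_cols)
    out[[col]] <- ifelse(is.na(out[[col]]), "", ifelse(out[[col]], "1", "0"))
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
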