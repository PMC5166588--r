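#' Derive Bernoulli sequential-scheme constants
#'
#' Computes the per-observation step constant `s` and the decision limit `h`
#' of the normalized Bernoulli CUSUM / LC-CUSUM from the acceptable failure
#' rate `p0`, the unacceptable failure rate `p1`, and the two error
#' probabilities, using the Wald (SPRT-approximation) boundaries.
#'
#' Order the two rates as `q_lo < q_hi`, with `q_lo` the failure rate under
#' the hypothesis favored by accumulating successes. With
#' `D = log(q_hi (1 - q_lo) / (q_lo (1 - q_hi)))` (the log-likelihood-ratio
#' increment of one failure minus that of one success), the scheme is
#' \deqn{s = \log\{(1-q_{lo})/(1-q_{hi})\} / D, \qquad
#'       h = \log\{(1-\beta)/\alpha\} / D.}
#' Each success moves the normalized score by `s` towards the holding barrier
#' at zero's far side, each failure by `1 - s` back towards it; the chart
#' signals when the score reaches `h` (in magnitude).
#'
#' For the monitoring phase `q_lo = p0 < p1 = q_hi` (failures push towards
#' the alarm). For the learning phase the roles reverse: successes accumulate
#' evidence of adequate performance, whose failure rate is the smaller of the
#' two supplied rates, so `q_lo = min(p0, p1)` and `q_hi = max(p0, p1)`. The
#' learning chart is conventionally plotted downwards (`plot_sign = -1`);
#' internally all scores are kept as positive magnitudes.
#'
#' @param p0 Acceptable failure rate, in (0, 1).
#' @param p1 Unacceptable failure rate, in (0, 1), different from `p0`.
#' @param alpha Type-I error rate, in (0, 1).
#' @param beta Type-II error rate, in (0, 1).
#' @param phase `"learning"` (LC-CUSUM, proficiency test) or `"monitoring"`
#'   (CUSUM, deterioration alarm).
#' @return A `monitoring_scheme` with elements `phase`, `p0`, `p1`, `alpha`,
#'   `beta`, `s`, `h` (positive magnitude) and `plot_sign`.
#' @examples
#' derive_scheme(0.105, 0.172, 0.05, 0.20, phase = "monitoring")  # h = 4.85
#' derive_scheme(0.272, 0.172, 0.05, 0.20, phase = "learning")    # h = 4.72
#' @export
derive_scheme <- function(p0, p1, alpha = 0.05, beta = 0.20,
                          phase = c("learning", "monitoring")) {
  phase <- match.arg(phase)
  for (v in list(p0 = p0, p1 = p1, alpha = alpha, beta = beta)) {
    if (!is.numeric(v) || length(v) != 1 || is.na(v))
      stop("derive_scheme: rates and error probabilities must be scalars",
           call. = FALSE)
  }
  if (p0 <= 0 || p0 >= 1 || p1 <= 0 || p1 >= 1)
    stop("derive_scheme: failure rates must lie strictly in (0, 1)",
         call. = FALSE)
  if (alpha <= 0 || alpha >= 1 || beta <= 0 || beta >= 1)
    stop("derive_scheme: alpha and beta must lie strictly in (0, 1)",
         call. = FALSE)
  if (p0 == p1)
    stop("derive_scheme: degenerate scheme, p0 must differ from p1",
         call. = FALSE)
  p0 <- as.numeric(p0); p1 <- as.numeric(p1)
  alpha <- as.numeric(alpha); beta <- as.numeric(beta)
  q_lo <- min(p0, p1)
  q_hi <- max(p0, p1)
  if (phase == "monitoring" && p0 > p1)
    stop("derive_scheme: monitoring phase requires p0 < p1", call. = FALSE)
  if (phase == "learning" && p1 > p0)
    stop("derive_scheme: learning phase requires the adequate-performance ",
         "rate p1 < p0", call. = FALSE)
  D <- log(q_hi * (1 - q_lo) / (q_lo * (1 - q_hi)))
  s <- log((1 - q_lo) / (1 - q_hi)) / D
  h <- log((1 - beta) / alpha) / D
  structure(list(phase = phase, p0 = p0, p1 = p1, alpha = alpha, beta = beta,
                 s = s, h = h,
                 plot_sign = if (phase == "learning") -1 else +1),
            class = "monitoring_scheme")
}

#' @export
print.monitoring_scheme <- function(x, ...) {
  cat(sprintf("%s scheme: p0 = %.3f, p1 = %.3f, alpha = %.2f, beta = %.2f\n",
              if (x$phase == "learning") "LC-CUSUM (learning)"
              else "CUSUM (monitoring)",
              x$p0, x$p1, x$alpha, x$beta))
  cat(sprintf("  step s = %.4f, decision limit h = %.2f (plotted %+.2f)\n",
              x$s, x$h, x$plot_sign * x$h))
  invisible(x)
}

#' Export a scheme as JSON
#'
#' @param scheme A [derive_scheme()] result.
#' @param path Output path; when `NULL`, returns the JSON string.
#' @export
write_scheme_json <- function(scheme, path = NULL) {
  stopifnot(inherits(scheme, "monitoring_scheme"))
  x <- scheme[c("phase", "p0", "p1", "alpha", "beta", "s", "h", "plot_sign")]
  if (is.null(path))
    return(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, na = "null"))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
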