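# Independent oracle for the sequential charts: accumulate the raw
# log-likelihood-ratio increments (not the normalized scores) with a holding
# barrier at zero and signal at log((1 - beta) / alpha). The normalized chart
# is this scheme divided by the increment span D, so signal indices must
# coincide.
llr_signal_oracle <- function(outcomes, p0, p1, alpha = 0.05, beta = 0.20,
                              phase = c("learning", "monitoring")) {
  phase <- match.arg(phase)
  q_lo <- min(p0, p1); q_hi <- max(p0, p1)
  if (phase == "monitoring") {
    # H1 "inadequate" (rate q_hi) against H0 "adequate" (rate q_lo)
    inc_fail <- log(q_hi / q_lo)
    inc_succ <- log((1 - q_hi) / (1 - q_lo))
  } else {
    # H1 "adequate" (rate q_lo) against H0 "inadequate" (rate q_hi)
    inc_fail <- log(q_lo / q_hi)
    inc_succ <- log((1 - q_lo) / (1 - q_hi))
  }
  limit <- log((1 - beta) / alpha)
  x <- 0
  for (i in seq_along(outcomes)) {
    x <- x + if (outcomes[i] == 1) inc_fail else inc_succ
    if (x < 0) x <- 0
    if (x >= limit - 1e-9) return(i)
  }
  NA_integer_
}

# Deterministic toy series: n cases, failures at the given 1-based positions,
# optional postoperative exams with the given number of anatomic failures
# (assigned to the lowest case indices).
toy_series <- function(n, failure_at = integer(0), cure_failures = NULL) {
  outcome <- as.integer(seq_len(n) %in% failure_at)
  df <- data.frame(case_index = seq_len(n), outcome = outcome,
                   followup_complete = TRUE)
  if (!is.null(cure_failures)) {
    df$post_Aa <- -3
    df$post_Ba <- ifelse(seq_len(n) <= cure_failures, 0, -2.8)
    df$post_TVL <- 8
  }
  case_series(df)
}

fig4_learning <- function() derive_scheme(0.272, 0.172, 0.05, 0.20,
                                          phase = "learning")
fig4_monitoring <- function() derive_scheme(0.105, 0.172, 0.05, 0.20,
                                            phase = "monitoring")
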