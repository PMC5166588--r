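#' POP-Q examination record
#'
#' Constructs a validated Pelvic Organ Prolapse Quantification (POP-Q) exam.
#' The six point measurements (`Aa`, `Ba`, `C`, `D`, `Ap`, `Bp`) are positions
#' in centimeters relative to the hymen, negative above (inside) the hymen,
#' positive beyond it. `TVL` (total vaginal length), `GH` (genital hiatus) and
#' `PB` (perineal body) are positive lengths in centimeters.
#'
#' Point values must lie in `[-3, TVL]`; `Aa` and `Ap` are anatomically
#' restricted to `[-3, +3]`. Points other than `Aa`, `Ba` and `TVL` may be
#' `NA` (absent), since only the anterior compartment is staged here.
#'
#' @param Aa,Ba,C,D,Ap,Bp Point positions (cm relative to hymen).
#' @param TVL Total vaginal length (cm, > 0).
#' @param GH,PB Genital hiatus and perineal body lengths (cm, > 0 or `NA`).
#' @param timing `"preoperative"` or `"12-month"` exam tag.
#' @return An object of class `popq_exam` (named list).
#' @examples
#' popq_exam(Aa = -3, Ba = -2.8, TVL = 8, timing = "12-month")
#' @export
popq_exam <- function(Aa, Ba, C = NA_real_, D = NA_real_, Ap = NA_real_,
                      Bp = NA_real_, TVL, GH = NA_real_, PB = NA_real_,
                      timing = c("preoperative", "12-month")) {
  timing <- match.arg(timing)
  exam <- list(Aa = as.numeric(Aa), Ba = as.numeric(Ba), C = as.numeric(C),
               D = as.numeric(D), Ap = as.numeric(Ap), Bp = as.numeric(Bp),
               TVL = as.numeric(TVL), GH = as.numeric(GH), PB = as.numeric(PB),
               timing = timing)
  validate_popq(exam)
  structure(exam, class = "popq_exam")
}

validate_popq <- function(exam) {
  tvl <- exam$TVL
  if (is.na(tvl) || tvl <= 0)
    stop("POP-Q exam: TVL must be a positive length (cm)", call. = FALSE)
  for (len in c("GH", "PB"))
    if (!is.na(exam[[len]]) && exam[[len]] <= 0)
      stop("POP-Q exam: ", len, " must be positive when present", call. = FALSE)
  for (pt in c("Aa", "Ba", "C", "D", "Ap", "Bp")) {
    v <- exam[[pt]]
    if (is.na(v)) next
    if (v < -3 || v > tvl)
      stop(sprintf("POP-Q exam: point %s = %g outside [-3, TVL = %g]",
                   pt, v, tvl), call. = FALSE)
    if (pt %in% c("Aa", "Ap") && v > 3)
      stop(sprintf("POP-Q exam: point %s = %g outside [-3, +3]", pt, v),
           call. = FALSE)
  }
  invisible(exam)
}

#' @export
print.popq_exam <- function(x, ...) {
  cat("POP-Q exam (", x$timing, ")\n", sep = "")
  pts <- unlist(x[c("Aa", "Ba", "C", "D", "Ap", "Bp", "TVL", "GH", "PB")])
  print(pts)
  invisible(x)
}

#' Anterior-compartment POP-Q stage
#'
#' Stages the anterior compartment (cystocele) on the 0-4 ordinal POP-Q scale
#' from the leading edge `max(Aa, Ba)`:
#' stage 0 iff `Aa = Ba = -3`; stage 1 iff the edge is below -1 cm (and not
#' stage 0); stage 2 iff the edge lies in `[-1, +1]`; stage 3 iff the edge is
#' beyond +1 but short of `TVL - 2`; stage 4 (complete eversion) iff the edge
#' reaches `TVL - 2` or beyond.
#'
#' Stage 0 here constrains only the anterior points; the full POP-Q stage 0
#' additionally constrains the apical points, which is outside the scope of a
#' per-compartment classifier.
#'
#' @param exam A [popq_exam()], or a numeric vector of `Aa` values (in which
#'   case `Ba` and `TVL` must be supplied; all three recycle together).
#' @param Ba,TVL Numeric vectors, used only when `exam` is numeric.
#' @return Integer stage(s) in 0..4.
#' @examples
#' stage_anterior(popq_exam(Aa = -3, Ba = -2.8, TVL = 8))  # stage 1
#' stage_anterior(c(-3, 1), Ba = c(-2.8, 2.5), TVL = c(8, 8))
#' @export
stage_anterior <- function(exam, Ba = NULL, TVL = NULL) {
  if (inherits(exam, "popq_exam")) {
    Aa <- exam$Aa; Ba <- exam$Ba; TVL <- exam$TVL
  } else {
    Aa <- as.numeric(exam)
  }
  if (is.null(Ba) || is.null(TVL))
    stop("stage_anterior: Ba and TVL are required", call. = FALSE)
  n <- max(length(Aa), length(Ba), length(TVL))
  Aa <- rep_len(Aa, n); Ba <- rep_len(Ba, n); TVL <- rep_len(TVL, n)
  missing_pt <- is.na(Aa) | is.na(Ba) | is.na(TVL)
  if (inherits(exam, "popq_exam") && any(missing_pt)) {
    miss <- c("Aa", "Ba", "TVL")[c(is.na(Aa[1]), is.na(Ba[1]), is.na(TVL[1]))]
    stop("stage_anterior: missing required point(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  edge <- pmax(Aa, Ba)
  edge[missing_pt] <- -3  # placeholder; masked to NA below
  Aa[missing_pt] <- -3; Ba[missing_pt] <- -3
  stage <- integer(n)
  stage[edge >= -1 & edge <= 1] <- 2L
  stage[edge > 1] <- ifelse(edge[edge > 1] >= TVL[edge > 1] - 2, 4L, 3L)
  stage[edge < -1] <- 1L
  stage[Aa == -3 & Ba == -3] <- 0L
  stage[missing_pt] <- NA_integer_
  stage
}

#' Anatomic cure of the anterior compartment
#'
#' Classifies a postoperative exam as an anatomic cure (anterior stage <= 1)
#' or a failure (stage >= 2, i.e. recurrent cystocele at or beyond -1 cm).
#'
#' @inheritParams stage_anterior
#' @return Character `"cure"` or `"failure"` (vectorized when given vectors).
#' @examples
#' classify_cure(popq_exam(Aa = -3, Ba = -3, TVL = 8, timing = "12-month"))
#' @export
classify_cure <- function(exam, Ba = NULL, TVL = NULL) {
  stage <- stage_anterior(exam, Ba = Ba, TVL = TVL)
  ifelse(is.na(stage), NA_character_,
         ifelse(stage <= 1L, "cure", "failure"))
}
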