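#' Define a MELD-family score
#'
#' A MELD-family score is an affine function of the natural logarithms of
#' (capped) serum creatinine, serum total bilirubin and the INR:
#' \deqn{intercept + c_{crea}\log(crea) + c_{bili}\log(bili) + c_{INR}\log(INR),}
#' with creatinine and bilirubin in mg/dL, per-biomarker lower/upper caps
#' applied before the log transform, and a dialysis rule that replaces the
#' measured creatinine by a fixed value for patients on biweekly dialysis.
#'
#' @param name label for the score.
#' @param intercept intercept in score points.
#' @param coef_crea,coef_bili,coef_inr score points per natural-log unit of
#'   the (capped) biomarker.
#' @param bounds named list with elements `creatinine`, `bilirubin`, `inr`,
#'   each a numeric `c(lower, upper)`; `Inf` upper means unbounded.
#' @param dialysis_crea creatinine value (mg/dL) substituted for patients on
#'   biweekly dialysis before capping, or `NA` for no substitution.
#' @return an object of class `meld_definition`.
#' @seealso [meld_definitions()] for the built-in UNOS-MELD, ReMELD and
#'   DynReMELD definitions, [meld_score()] to evaluate a definition.
#' @export
meld_definition <- function(name, intercept, coef_crea, coef_bili, coef_inr,
                            bounds, dialysis_crea = NA_real_) {
  stopifnot(is.character(name), length(name) == 1L)
  coefs <- c(intercept, coef_crea, coef_bili, coef_inr)
  if (!all(is.finite(coefs)))
    stop("score intercept and coefficients must be finite")
  bounds <- bounds[c("creatinine", "bilirubin", "inr")]
  for (nm in names(bounds)) {
    b <- bounds[[nm]]
    if (length(b) != 2L || !is.numeric(b) || is.na(b[1L]) || is.na(b[2L]))
      stop("bounds$", nm, " must be numeric c(lower, upper)")
    if (b[1L] >= b[2L])
      stop("bounds$", nm, ": lower bound must be below upper bound")
  }
  structure(
    list(name = name, intercept = intercept,
         coef_crea = coef_crea, coef_bili = coef_bili, coef_inr = coef_inr,
         bounds = bounds, dialysis_crea = dialysis_crea),
    class = "meld_definition")
}

#' @export
print.meld_definition <- function(x, ...) {
  fmt_b <- function(b) {
    up <- if (is.finite(b[2L])) format(b[2L]) else "unbounded"
    paste0("[", format(b[1L]), ", ", up, "]")
  }
  cat(x$name, ":\n  ", format(x$intercept),
      " + ", format(x$coef_crea), " log(crea)",
      " + ", format(x$coef_bili), " log(bili)",
      " + ", format(x$coef_inr), " log(INR)\n", sep = "")
  cat("  creatinine ", fmt_b(x$bounds$creatinine),
      ", bilirubin ", fmt_b(x$bounds$bilirubin),
      ", INR ", fmt_b(x$bounds$inr), "\n", sep = "")
  if (!is.na(x$dialysis_crea))
    cat("  on biweekly dialysis: creatinine set to ",
        format(x$dialysis_crea), " mg/dL\n", sep = "")
  invisible(x)
}

#' Clamp a biomarker value to its caps
#'
#' @param value biomarker value(s) in native units.
#' @param bounds numeric `c(lower, upper)`; `Inf` upper allowed.
#' @return the value(s) clamped to `[lower, upper]`.
#' @export
apply_caps <- function(value, bounds) {
  pmin(pmax(value, bounds[1L]), bounds[2L])
}

#' Evaluate a MELD-family score
#'
#' Applies the dialysis substitution first (when `dialysis` is `TRUE` and the
#' definition carries a substitution value), then the per-biomarker caps, and
#' finally the affine log-linear equation.  The returned score is continuous
#' (unrounded); Eurotransplant-style integer display is obtained with
#' `round()`.
#'
#' @param definition a [meld_definition()].
#' @param creatinine,bilirubin,inr biomarker values (vectorized), all > 0.
#' @param dialysis logical (vectorized): on biweekly dialysis?
#' @return numeric vector of score points.
#' @examples
#' defs <- meld_definitions()
#' meld_score(defs$unos, 1.0, 1.0, 1.0)       # the UNOS-MELD intercept
#' meld_score(defs$unos, 1.2, 1.0, 1.0, dialysis = TRUE)
#' @export
meld_score <- function(definition, creatinine, bilirubin, inr,
                       dialysis = FALSE) {
  stopifnot(inherits(definition, "meld_definition"))
  n <- max(length(creatinine), length(bilirubin), length(inr),
           length(dialysis))
  creatinine <- rep_len(creatinine, n)
  bilirubin <- rep_len(bilirubin, n)
  inr <- rep_len(inr, n)
  dialysis <- rep_len(as.logical(dialysis), n)
  if (!is.na(definition$dialysis_crea))
    creatinine[dialysis] <- definition$dialysis_crea
  cr <- apply_caps(creatinine, definition$bounds$creatinine)
  bi <- apply_caps(bilirubin, definition$bounds$bilirubin)
  ir <- apply_caps(inr, definition$bounds$inr)
  if (any(cr <= 0 | bi <= 0 | ir <= 0, na.rm = TRUE))
    stop("non-positive biomarker after capping; malformed score definition")
  definition$intercept +
    definition$coef_crea * log(cr) +
    definition$coef_bili * log(bi) +
    definition$coef_inr * log(ir)
}

#' Built-in score definitions
#'
#' The three MELD-family scores shipped with the package:
#' \describe{
#'   \item{`unos`}{UNOS-MELD, the score used in Eurotransplant allocation:
#'     `6.43 + 9.57 log(crea) + 3.78 log(bili) + 11.20 log(INR)`, creatinine
#'     capped at 4.0 mg/dL, lower limit 1.0 on all biomarkers, creatinine set
#'     to 4.0 on biweekly dialysis.}
#'   \item{`remeld`}{ReMELD, a prior Eurotransplant-specific revision:
#'     `8.422 + 7.728 log(crea) + 3.446 log(bili) + 10.597 log(INR)`,
#'     bilirubin 0.3--27 mg/dL, INR 0.1--2.6, creatinine 0.7--2.5 mg/dL and
#'     set to 2.5 on biweekly dialysis.}
#'   \item{`dynremeld`}{DynReMELD, revised from calendar-time cross-sections
#'     with IPCW: `8.50 + 9.12 log(crea) + 4.14 log(bili) + 9.42 log(INR)`,
#'     creatinine 0.8--2.5 mg/dL, bilirubin 0.6--55 mg/dL, INR 1.0--3.0,
#'     creatinine set to the upper cap (2.5) on biweekly dialysis.}
#' }
#'
#' @return named list of [meld_definition()] objects.
#' @export
meld_definitions <- function() {
  list(
    unos = meld_definition(
      "UNOS-MELD", 6.43, 9.57, 3.78, 11.20,
      bounds = list(creatinine = c(1.0, 4.0),
                    bilirubin = c(1.0, Inf),
                    inr = c(1.0, Inf)),
      dialysis_crea = 4.0),
    remeld = meld_definition(
      "ReMELD", 8.422, 7.728, 3.446, 10.597,
      bounds = list(creatinine = c(0.7, 2.5),
                    bilirubin = c(0.3, 27),
                    inr = c(0.1, 2.6)),
      dialysis_crea = 2.5),
    dynremeld = meld_definition(
      "DynReMELD", 8.50, 9.12, 4.14, 9.42,
      bounds = list(creatinine = c(0.8, 2.5),
                    bilirubin = c(0.6, 55),
                    inr = c(1.0, 3.0)),
      dialysis_crea = 2.5))
}

#' Relative weight of each biomarker in a score
#'
#' Sharma-style component weights: the increase in score per one-standard-
#' deviation increase of a (log, capped) biomarker, relative to the summed
#' increase over all three biomarkers,
#' \deqn{w_k = c_k sd(\log x_k) / \sum_j c_j sd(\log x_j).}
#' Standard deviations are taken over the supplied cohort of reports after
#' applying the definition's dialysis rule and caps.
#'
#' @param definition a [meld_definition()].
#' @param reports data.frame with columns `creatinine`, `bilirubin`, `inr`,
#'   `dialysis` (at least 2 rows).
#' @return named numeric vector `(creatinine, bilirubin, inr)` summing to 1.
#' @export
component_weights <- function(definition, reports) {
  stopifnot(is.data.frame(reports), nrow(reports) >= 2L)
  cr <- reports$creatinine
  if (!is.na(definition$dialysis_crea))
    cr[as.logical(reports$dialysis)] <- definition$dialysis_crea
  s <- c(
    creatinine = definition$coef_crea *
      stats::sd(log(apply_caps(cr, definition$bounds$creatinine))),
    bilirubin = definition$coef_bili *
      stats::sd(log(apply_caps(reports$bilirubin, definition$bounds$bilirubin))),
    inr = definition$coef_inr *
      stats::sd(log(apply_caps(reports$inr, definition$bounds$inr))))
  if (any(s == 0))
    stop("zero variance in a score component over this cohort")
  s / sum(s)
}
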