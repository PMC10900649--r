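# Score revision: weighted stratified 90-day time-stopped Cox models with
# optional score offset, profile-likelihood cap optimization, quantile
# matching to the MELD point scale, and derivation of a deployable score.

# model covariates: creatinine set to 1.0 under dialysis (log 1 = 0), so
# renal function is scored through the dialysis indicator for dialysis
# patients; then caps; then logs
mortality_covariates <- function(d, caps = NULL,
                                 dialysis_as_covariate = TRUE) {
  cr <- d$creatinine
  cr[d$dialysis == 1L] <- 1.0
  bi <- d$bilirubin
  ir <- d$inr
  if (!is.null(caps)) {
    cr <- apply_caps(cr, caps$creatinine)
    bi <- apply_caps(bi, caps$bilirubin)
    ir <- apply_caps(ir, caps$inr)
  }
  out <- data.frame(lcrea = log(cr), lbili = log(bi), linr = log(ir))
  if (dialysis_as_covariate) out$dialysis <- as.numeric(d$dialysis)
  out
}

#' Fit the (weighted) stratified 90-day mortality model
#'
#' Maximizes the stratified Cox partial likelihood (Efron ties) for
#' waitlist death over log capped creatinine (with creatinine set to 1.0
#' under biweekly dialysis), log capped bilirubin, log capped INR and the
#' dialysis indicator.  Accepts plain analysis rows (unweighted fit) or
#' IPCW-weighted counting-process rows from [compute_weights()].  When an
#' offset score is supplied its points are converted to the log-hazard
#' scale (divided by `offset_scale`) and entered as a fixed offset; the
#' likelihood-ratio statistic is then for the covariates added on top of
#' the offset.
#'
#' Standard errors are reported both model-based and cluster-robust by
#' patient; cross-section rows from one patient overlap in follow-up, so
#' the robust ones are the honest choice for inference.
#'
#' @param rows `cs_rows` or `ipcw_rows`.
#' @param caps named list of `c(lower, upper)` per biomarker (as in a
#'   [meld_definition()] `bounds`), or `NULL` for no capping.
#' @param dialysis_as_covariate include the dialysis indicator (default
#'   TRUE; offset fits conventionally exclude it, giving a 3-df test).
#' @param offset_score optional [meld_definition()] used as offset.
#' @param offset_scale points-per-log-hazard-unit scale of the offset
#'   score; `NULL` estimates it by quantile-matching the offset score
#'   against the linear predictor of the no-offset fit on the same rows.
#' @param stratify_by_cross_section keep the `country:cs_date` stratum of
#'   cross-section rows (default); `FALSE` re-stratifies by country only.
#' @return object of class `meld_coxfit`: coefficients, model-based and
#'   robust standard errors, covariance, log partial likelihoods,
#'   LR statistic and df, numbers of rows/events/strata-dropped, the caps
#'   and offset actually used, and the underlying `coxph` fit.
#' @export
fit_mortality_model <- function(rows, caps = NULL,
                                dialysis_as_covariate = TRUE,
                                offset_score = NULL, offset_scale = NULL,
                                stratify_by_cross_section = TRUE) {
  stopifnot(nrow(rows) > 0L)
  weighted <- inherits(rows, "ipcw_rows")
  d <- as.data.frame(rows)
  xx <- mortality_covariates(d, caps, dialysis_as_covariate)
  if (qr(as.matrix(xx))$rank < ncol(xx))
    stop("singular design: covariates are collinear on these rows")
  strat <- if (stratify_by_cross_section) d$stratum else d$country
  dd <- cbind(xx, stratum = strat, patient_id = d$patient_id)
  if (weighted) {
    dd$tstart <- d$tstart; dd$tstop <- d$tstop; dd$ev <- d$ev
    dd$w <- d$weight
    surv <- "survival::Surv(tstart, tstop, ev)"
  } else {
    dd$tstop <- d$time_days; dd$ev <- as.integer(d$event)
    dd$w <- 1
    surv <- "survival::Surv(tstop, ev)"
  }
  off_info <- NULL
  if (!is.null(offset_score)) {
    pts <- meld_score(offset_score, d$creatinine, d$bilirubin, d$inr,
                      d$dialysis == 1L)
    if (is.null(offset_scale)) {
      base_fit <- fit_mortality_model(
        rows, caps = caps, dialysis_as_covariate = TRUE,
        stratify_by_cross_section = stratify_by_cross_section)
      qm <- quantile_match(predict_lp(base_fit, d), pts)
      offset_scale <- qm$a
    }
    dd$off <- pts / offset_scale
    off_info <- list(score = offset_score$name, scale = offset_scale)
  }
  fml <- stats::as.formula(paste(
    surv, "~", paste(names(xx), collapse = " + "),
    "+ strata(stratum) + cluster(patient_id)",
    if (!is.null(offset_score)) "+ offset(off)"))
  fit <- survival::coxph(fml, data = dd, weights = w, ties = "efron",
                         model = FALSE, x = FALSE, y = FALSE)
  beta <- stats::coef(fit)
  lr <- 2 * diff(fit$loglik)
  # strata without events contribute nothing to the partial likelihood
  ev_by_str <- tapply(dd$ev * dd$w, dd$stratum, sum)
  res <- list(
    coefficients = beta,
    se = sqrt(diag(if (is.null(fit$naive.var)) fit$var else fit$naive.var)),
    robust_se = sqrt(diag(fit$var)),
    var = fit$var,
    naive_var = if (is.null(fit$naive.var)) fit$var else fit$naive.var,
    loglik = fit$loglik,
    lr_statistic = lr,
    df = length(beta),
    n = nrow(d), n_events = sum(dd$ev),
    n_strata_no_events = sum(ev_by_str == 0, na.rm = TRUE),
    weighted = weighted,
    caps = caps, dialysis_as_covariate = dialysis_as_covariate,
    offset = off_info,
    cox = fit)
  class(res) <- "meld_coxfit"
  res
}

#' @export
print.meld_coxfit <- function(x, ...) {
  cat("Stratified 90-day waitlist mortality Cox fit",
      if (x$weighted) "(IPCW-weighted)" else "(unweighted)", "\n")
  tab <- data.frame(coef = x$coefficients, se = x$se,
                    robust_se = x$robust_se)
  print(round(tab, 4))
  if (!is.null(x$offset))
    cat("Offset:", x$offset$score, "/", format(x$offset$scale), "\n")
  cat("LR statistic ", format(round(x$lr_statistic, 1)), " (df = ",
      x$df, "), n = ", x$n, ", events = ", round(x$n_events, 1),
      "\n", sep = "")
  invisible(x)
}

#' Linear predictor of a mortality fit on analysis rows
#'
#' Rebuilds the fit's covariates (same caps and dialysis handling) on new
#' rows and returns `X %*% beta` (any offset excluded).
#'
#' @param fit a [fit_mortality_model()] result.
#' @param rows analysis rows.
#' @return numeric vector.
#' @export
predict_lp <- function(fit, rows) {
  xx <- mortality_covariates(as.data.frame(rows), fit$caps,
                             fit$dialysis_as_covariate)
  as.vector(as.matrix(xx) %*% fit$coefficients)
}

#' Likelihood-ratio test
#'
#' `statistic = 2 (loglik_full - loglik_null)` referred to a chi-square
#' upper tail.  Accepts either two log likelihoods, a fitted
#' [fit_mortality_model()] (whose own LR statistic and df are used), or a
#' ready-made statistic.
#'
#' @param full a `meld_coxfit`, a full-model log likelihood, or (when
#'   `null_loglik` is `NULL`) the LR statistic itself.
#' @param null_loglik log likelihood of the nested null (offset-only or
#'   empty) model, or `NULL`.
#' @param df degrees of freedom of the test.
#' @return list `(statistic, df, p_value)`.
#' @examples
#' lr_test(4.1, df = 3)   # p ~ 0.25
#' lr_test(801, df = 3)   # p < 0.001
#' @export
lr_test <- function(full, null_loglik = NULL, df = NULL) {
  if (inherits(full, "meld_coxfit")) {
    if (is.null(null_loglik)) {
      stat <- full$lr_statistic
      if (is.null(df)) df <- full$df
    } else {
      stat <- 2 * (full$loglik[2L] - null_loglik)
    }
  } else if (is.null(null_loglik)) {
    stat <- full
  } else {
    stat <- 2 * (full - null_loglik)
  }
  if (is.null(df)) stop("df must be given")
  if (stat < -1e-6)
    stop("negative LR statistic: models not nested or not converged")
  stat <- max(stat, 0)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

default_cap_grid <- function() {
  list(creatinine = list(lower = c(0.6, 0.8, 1.0),
                         upper = c(2.0, 2.5, 3.0, 4.0)),
       bilirubin = list(lower = c(0.3, 0.6, 1.0),
                        upper = c(27, 55, Inf)),
       inr = list(lower = c(0.8, 1.0, 1.2),
                  upper = c(2.6, 3.0, Inf)))
}

#' Optimize biomarker caps by profile partial likelihood
#'
#' Coordinate-wise search over candidate (lower, upper) cap pairs:
#' creatinine, then bilirubin, then INR, each optimized with the others
#' held at their current values, sweeping until no change (at most
#' `max_sweeps` sweeps).  The multivariable model is refitted at every
#' candidate; ties in log likelihood break toward wider bounds.
#'
#' @param rows analysis rows (plain or IPCW-weighted).
#' @param search_grid per-biomarker candidate values: named list with
#'   elements `creatinine`, `bilirubin`, `inr`, each
#'   `list(lower = ..., upper = ...)`.
#' @param start starting caps; defaults to the widest candidates.
#' @param max_sweeps maximum coordinate sweeps (default 3).
#' @param ... passed to [fit_mortality_model()].
#' @return object of class `cap_search`: `caps` (the optimum), `loglik`,
#'   and `profile` (every evaluated candidate).
#' @export
optimize_caps <- function(rows, search_grid = default_cap_grid(),
                          start = NULL, max_sweeps = 3L, ...) {
  widest <- function(g) c(min(g$lower), max(g$upper))
  caps <- if (is.null(start))
    lapply(search_grid, widest) else start
  profile <- list()
  eval_ll <- function(caps) {
    fit <- fit_mortality_model(rows, caps = caps, ...)
    fit$loglik[2L]
  }
  best_ll <- eval_ll(caps)
  for (sweep in seq_len(max_sweeps)) {
    changed <- FALSE
    for (bm in c("creatinine", "bilirubin", "inr")) {
      g <- search_grid[[bm]]
      cand <- expand.grid(lower = g$lower, upper = g$upper)
      cand <- cand[cand$lower < cand$upper, , drop = FALSE]
      # widest first, so equal log likelihoods keep the wider pair
      cand <- cand[order(-(cand$upper - cand$lower)), , drop = FALSE]
      for (i in seq_len(nrow(cand))) {
        trial <- caps
        trial[[bm]] <- c(cand$lower[i], cand$upper[i])
        ll <- if (identical(trial[[bm]], caps[[bm]])) best_ll
              else eval_ll(trial)
        profile[[length(profile) + 1L]] <- data.frame(
          sweep = sweep, biomarker = bm,
          lower = cand$lower[i], upper = cand$upper[i], loglik = ll)
        if (ll > best_ll + 1e-9) {
          best_ll <- ll
          caps <- trial
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  structure(list(caps = caps, loglik = best_ll,
                 profile = do.call(rbind, profile)),
            class = "cap_search")
}

#' @export
print.cap_search <- function(x, ...) {
  cat("Profile-likelihood cap search (log likelihood ",
      format(x$loglik), "):\n", sep = "")
  for (bm in names(x$caps))
    cat("  ", bm, ": ", x$caps[[bm]][1L], " - ", x$caps[[bm]][2L],
        "\n", sep = "")
  invisible(x)
}

#' Affine quantile matching of a linear predictor to a reference score
#'
#' Least-squares fit of reference-score quantiles on linear-predictor
#' quantiles over a percentile grid: returns `a` (scale, points per
#' log-hazard unit) and `b` (shift) with
#' `reference ~ a * linear_predictor + b`.
#'
#' @param linear_predictor fitted linear-predictor values over a cohort.
#' @param reference_scores the same cohort's reference (e.g. UNOS-MELD)
#'   scores.
#' @param probs percentile grid (default 1--99).
#' @return list `(a, b)`.
#' @export
quantile_match <- function(linear_predictor, reference_scores,
                           probs = (1:99) / 100) {
  if (stats::sd(linear_predictor) == 0)
    stop("degenerate linear predictor: zero variance")
  qlp <- stats::quantile(linear_predictor, probs, names = FALSE)
  qref <- stats::quantile(reference_scores, probs, names = FALSE)
  cf <- stats::coef(stats::lm(qref ~ qlp))
  list(a = unname(cf[2L]), b = unname(cf[1L]))
}

#' Derive a deployable MELD-family score from a mortality fit
#'
#' Rescales the three biomarker coefficients to the MELD point scale
#' (`a * beta`, rounded to 2 decimals, intercept `b`), attaches the caps,
#' and replaces the fitted dialysis coefficient by the clinical
#' substitution rule "creatinine = upper cap under dialysis" — justified
#' when the dialysis-equivalent creatinine
#' `exp(beta_dialysis / beta_creatinine)` is close to the upper cap.
#'
#' @param fit a [fit_mortality_model()] result (coefficients `lcrea`,
#'   `lbili`, `linr`, optionally `dialysis`).
#' @param scale,shift the quantile-match `a` and `b` (see
#'   [quantile_match()]).
#' @param caps per-biomarker bounds for the deployed score; defaults to
#'   the fit's caps.
#' @param name score label.
#' @return a [meld_definition()].
#' @export
derive_score <- function(fit, scale, shift, caps = fit$caps,
                         name = "revised score") {
  stopifnot(inherits(fit, "meld_coxfit"), !is.null(caps))
  beta <- fit$coefficients
  meld_definition(
    name,
    intercept = round(shift, 2),
    coef_crea = round(scale * beta[["lcrea"]], 2),
    coef_bili = round(scale * beta[["lbili"]], 2),
    coef_inr = round(scale * beta[["linr"]], 2),
    bounds = caps,
    dialysis_crea = caps$creatinine[2L])
}

#' Creatinine level with the same priority as biweekly dialysis
#'
#' `exp(coef_dialysis / coef_creatinine)` from a mortality fit: the
#' creatinine (mg/dL) at which the log-creatinine term equals the
#' dialysis term, used to justify scoring dialysis as creatinine at the
#' upper cap.
#'
#' @param coef_dialysis,coef_creatinine either a `meld_coxfit` as first
#'   argument, or the two Cox coefficients.
#' @return creatinine in mg/dL.
#' @export
dialysis_equivalent_creatinine <- function(coef_dialysis,
                                           coef_creatinine = NULL) {
  if (inherits(coef_dialysis, "meld_coxfit")) {
    b <- coef_dialysis$coefficients
    return(exp(b[["dialysis"]] / b[["lcrea"]]))
  }
  exp(coef_dialysis / coef_creatinine)
}
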