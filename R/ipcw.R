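# Inverse probability of censoring weighting for the two censoring
# causes that act on the waitlist: transplantation (IPCW-T) and delisting
# (IPCW-D).  Both are modelled cause-specifically with extended
# (counting-process, time-varying covariate) Cox models; the joint weight
# at time t is 1 / (S_T(t | history) * S_D(t | history)) under conditional
# independence of the two causes given the covariate history, optionally
# stabilized by the marginal censoring survival and truncated at an upper
# quantile.

# Split analysis rows at every biomarker report between the cross-section
# date and the row's end of follow-up; covariates on each interval are the
# values in force at the interval start.
censoring_counting_data <- function(rows, x, time_varying = TRUE) {
  rows <- data.table::as.data.table(rows)
  rows[, "row_id" := seq_len(nrow(rows))]
  base <- rows[, c("row_id", "patient_id", "country", "stratum", "cs_date",
                   "creatinine", "bilirubin", "inr", "dialysis",
                   "time_days", "event", "censor_cause")]
  seg0 <- data.table::copy(base)
  seg0[, "t" := 0L]
  if (time_varying) {
    reps <- data.table::as.data.table(x$reports)
    cand <- merge(
      base[, c("row_id", "patient_id", "cs_date", "time_days")],
      reps, by = "patient_id", allow.cartesian = TRUE)
    cand <- cand[cand$report_date > cand$cs_date &
                   cand$report_date < cand$cs_date + cand$time_days]
    if (nrow(cand)) {
      cand[, "t" := as.integer(cand$report_date - cand$cs_date)]
      # last report of a day wins
      data.table::setorderv(cand, c("row_id", "t"))
      cand <- cand[!duplicated(cand[, c("row_id", "t")],
                               fromLast = TRUE)]
      segk <- merge(
        cand[, c("row_id", "t", "creatinine", "bilirubin", "inr",
                 "dialysis")],
        base[, c("row_id", "patient_id", "country", "stratum", "cs_date",
                 "time_days", "event", "censor_cause")],
        by = "row_id")
      seg0 <- rbind(seg0, segk, use.names = TRUE)
    }
  }
  data.table::setorderv(seg0, c("row_id", "t"))
  seg0[, "tstart" := seg0$t]
  tstop <- c(seg0$t[-1L], 0L)
  last <- !duplicated(seg0$row_id, fromLast = TRUE)
  tstop[last] <- seg0$time_days[last]
  seg0[, "tstop" := tstop]
  seg0[, "last" := last]
  seg0 <- seg0[seg0$tstop > seg0$tstart]
  seg0[, "last" := !duplicated(seg0$row_id, fromLast = TRUE)]
  seg0
}

# allocation-scale covariate transform: the UNOS-MELD component
# transforms (dialysis-substituted, capped, logged)
alloc_covariates <- function(d) {
  cr <- d$creatinine
  cr[d$dialysis == 1L] <- 4.0
  data.frame(
    lcrea = log(pmin(pmax(cr, 1.0), 4.0)),
    lbili = log(pmax(d$bilirubin, 1.0)),
    linr = log(pmax(d$inr, 1.0)),
    dialysis = as.numeric(d$dialysis))
}

log_covariates <- function(d) {
  data.frame(lcrea = log(d$creatinine), lbili = log(d$bilirubin),
             linr = log(d$inr), dialysis = as.numeric(d$dialysis))
}

#' Fit a cause-specific censoring model
#'
#' Extended Cox model for one censoring cause (transplantation or
#' delisting) on the cross-section analysis rows, with covariates updated
#' at every biomarker report after the cross-section date and all other
#' exits treated as censoring.  Stratified by country and pooled over
#' cross-sections so per-stratum risk sets stay estimable.
#'
#' @param rows analysis rows from [build_cross_section_dataset()] or
#'   [build_from_registration_dataset()].
#' @param x the [registry()] the rows came from (supplies the
#'   post-cross-section reports).
#' @param cause `"transplant"` or `"delisting"`.
#' @param covariates `"allocation"` (default): log biomarkers on the
#'   allocation scale, i.e. UNOS-capped with the dialysis creatinine
#'   substitution, plus the dialysis flag — transplant selection acts on
#'   the allocation score, so this is the natural scale; `"log"`: raw log
#'   biomarkers plus dialysis; `"none"`: no covariates (stratified
#'   Nelson–Aalen baseline only).
#' @param time_varying update covariates at post-cross-section reports
#'   (default) or freeze them at their cross-section values.
#' @return object of class `censoring_model`: the `coxph` fit (or NULL for
#'   `"none"`), per-country baseline cumulative hazard step functions, and
#'   the covariate codebook.
#' @export
fit_censoring_model <- function(rows, x,
                                cause = c("transplant", "delisting"),
                                covariates = c("allocation", "log", "none"),
                                time_varying = TRUE) {
  cause <- match.arg(cause)
  covariates <- match.arg(covariates)
  long <- censoring_counting_data(rows, x, time_varying = time_varying)
  long[, "ev" := as.integer(long$last & !is.na(long$censor_cause) &
                              long$censor_cause == cause)]
  if (sum(long$ev) == 0L)
    stop("cannot estimate weights: no ", cause, " events in these rows")
  long[, "cstratum" := factor(long$country)]
  trans <- switch(covariates, allocation = alloc_covariates,
                  log = log_covariates, none = NULL)
  if (covariates == "none") {
    sf <- survival::survfit(
      survival::Surv(tstart, tstop, ev) ~ cstratum,
      data = long, ctype = 1)
    bh <- nelson_aalen_table(sf, levels(long$cstratum))
    fit <- NULL
    coefs <- numeric(0)
  } else {
    xx <- trans(long)
    dd <- cbind(long[, c("tstart", "tstop", "ev", "cstratum",
                         "patient_id")], xx)
    fit <- survival::coxph(
      survival::Surv(tstart, tstop, ev) ~ lcrea + lbili + linr +
        dialysis + strata(cstratum) + cluster(patient_id),
      data = dd, ties = "efron")
    coefs <- stats::coef(fit)
    bh0 <- survival::basehaz(fit, centered = FALSE)
    bh <- split(bh0[, c("time", "hazard")],
                sub("^cstratum=", "", as.character(bh0$strata)))
  }
  structure(list(cause = cause, fit = fit, coefficients = coefs,
                 robust_se = if (is.null(fit)) numeric(0)
                             else sqrt(diag(fit$var)),
                 covariates = covariates, transform = trans,
                 basehaz = bh, time_varying = time_varying),
            class = "censoring_model")
}

#' @export
print.censoring_model <- function(x, ...) {
  cat("Cause-specific censoring model (", x$cause, "), covariates: ",
      x$covariates, "\n", sep = "")
  if (length(x$coefficients)) print(x$coefficients)
  invisible(x)
}

# per-stratum Nelson-Aalen cumulative hazard tables from a survfit
nelson_aalen_table <- function(sf, stratum_levels) {
  dat <- summary(sf, censored = TRUE)
  strat <- if (is.null(dat$strata)) rep(stratum_levels[1L],
                                        length(dat$time))
           else sub("^cstratum=", "", as.character(dat$strata))
  ch <- dat$cumhaz
  out <- split(data.frame(time = dat$time, hazard = ch), strat)
  out
}

# H0(t) lookup: right-continuous step function, 0 before the first event
cumhaz_at <- function(bh_stratum, t) {
  if (is.null(bh_stratum) || nrow(bh_stratum) == 0L)
    return(rep.int(0, length(t)))
  idx <- findInterval(t, bh_stratum$time)
  c(0, bh_stratum$hazard)[idx + 1L]
}

# linear predictor of a censoring model on a counting-data segment table
censoring_lp <- function(model, long) {
  if (model$covariates == "none") return(rep.int(0, nrow(long)))
  xx <- model$transform(long)
  as.vector(as.matrix(xx) %*% model$coefficients)
}

# cumulative cause-specific hazard at each segment end, given the
# covariate history (sum of per-segment baseline increments times exp(lp))
cumhaz_history <- function(model, long) {
  lp <- censoring_lp(model, long)
  inc <- numeric(nrow(long))
  for (s in unique(long$country)) {
    i <- which(long$country == s)
    bh <- model$basehaz[[s]]
    inc[i] <- (cumhaz_at(bh, long$tstop[i]) -
                 cumhaz_at(bh, long$tstart[i])) * exp(lp[i])
  }
  stats::ave(inc, long$row_id, FUN = cumsum)
}

#' Attach joint IPCW-T x IPCW-D weights to analysis rows
#'
#' Expands each analysis row into counting-process intervals split at
#' every post-cross-section biomarker report and attaches the joint
#' censoring weight evaluated at each interval end,
#' \deqn{w(t) = 1 / (S_T(t | history)\, S_D(t | history)),}
#' optionally stabilized by the marginal (covariate-free, per-country)
#' censoring survival \eqn{\bar S_T(t)\bar S_D(t)} and truncated at an
#' upper quantile of the interval weight distribution.
#'
#' @param rows analysis rows (see [build_cross_section_dataset()]).
#' @param model_T,model_D fitted [fit_censoring_model()] objects for
#'   transplantation and delisting.
#' @param x the [registry()] behind the rows.
#' @param stabilize multiply by the marginal censoring survival (default
#'   TRUE).
#' @param truncation_quantile truncate interval weights at this quantile
#'   (default 0.99); `NULL` for no truncation.
#' @param max_hazard_step weights are step functions evaluated at
#'   interval ends; a row at risk at an event time inside an interval
#'   would carry up to the interval's full censoring-hazard increment in
#'   excess weight, differentially by severity.  Intervals are therefore
#'   subdivided so that no piece accumulates more than this much joint
#'   censoring cumulative hazard (default 0.02), with pieces never
#'   shorter than 1 day (times are day-granular, so 1-day pieces make
#'   the weight exact at every event time) and never longer than
#'   `max_interval_days`.
#' @param max_interval_days upper bound on piece length in days
#'   (default 14; `Inf` with `max_hazard_step = Inf` disables
#'   subdivision).
#' @return data.frame of class `ipcw_rows`: the row columns plus
#'   `row_id`, `tstart`, `tstop`, `weight` and the per-interval death
#'   indicator `ev` (1 only on an event row's final interval).
#' @export
compute_weights <- function(rows, model_T, model_D, x,
                            stabilize = TRUE,
                            truncation_quantile = 0.99,
                            max_hazard_step = 0.02,
                            max_interval_days = 14L) {
  stopifnot(inherits(model_T, "censoring_model"),
            inherits(model_D, "censoring_model"))
  tv <- model_T$time_varying || model_D$time_varying
  long <- censoring_counting_data(rows, x, time_varying = tv)
  # first pass: per-interval joint censoring hazard rate, used to set
  # the subdivision resolution
  if (is.finite(max_hazard_step) || is.finite(max_interval_days)) {
    dH <- ave_increment(model_T, long) + ave_increment(model_D, long)
    len <- long$tstop - long$tstart
    rate <- ifelse(len > 0, dH / len, 0)
    target <- pmin(pmax(floor(max_hazard_step / pmax(rate, 1e-12)), 1),
                   max_interval_days)
    long <- subdivide_intervals(long, target)
  }
  H_T <- cumhaz_history(model_T, long)
  H_D <- cumhaz_history(model_D, long)
  w <- exp(H_T + H_D)
  if (stabilize) {
    marg_T <- marginal_cumhaz(long, "transplant")
    marg_D <- marginal_cumhaz(long, "delisting")
    Hm <- numeric(nrow(long))
    for (s in unique(long$country)) {
      i <- which(long$country == s)
      Hm[i] <- cumhaz_at(marg_T[[s]], long$tstop[i]) +
        cumhaz_at(marg_D[[s]], long$tstop[i])
    }
    w <- w * exp(-Hm)
  }
  if (!is.null(truncation_quantile))
    w <- pmin(w, stats::quantile(w, truncation_quantile, names = FALSE))
  if (any(!is.finite(w))) {
    bad <- long$row_id[which(!is.finite(w))[1L]]
    stop("non-finite censoring weight for analysis row ", bad)
  }
  long[, "weight" := w]
  long[, "ev" := as.integer(long$last & long$event)]
  # the mortality model is partly conditional: its covariates stay
  # frozen at their cross-section values on every interval (the
  # post-cross-section reports enter the censoring models only)
  rows_dt <- data.table::as.data.table(rows)
  rows_dt[, "row_id" := seq_len(nrow(rows_dt))]
  base_cov <- rows_dt[, c("row_id", "creatinine", "bilirubin", "inr",
                          "dialysis")]
  idx <- match(long$row_id, base_cov$row_id)
  long[, c("creatinine", "bilirubin", "inr", "dialysis") :=
         list(base_cov$creatinine[idx], base_cov$bilirubin[idx],
              base_cov$inr[idx], base_cov$dialysis[idx])]
  res <- as.data.frame(long)
  class(res) <- c("ipcw_rows", "data.frame")
  attr(res, "stabilized") <- stabilize
  attr(res, "truncation_quantile") <- truncation_quantile
  res
}

# per-interval censoring cumulative-hazard increment under a model
ave_increment <- function(model, long) {
  lp <- censoring_lp(model, long)
  inc <- numeric(nrow(long))
  for (s in unique(long$country)) {
    i <- which(long$country == s)
    bh <- model$basehaz[[s]]
    inc[i] <- (cumhaz_at(bh, long$tstop[i]) -
                 cumhaz_at(bh, long$tstart[i])) * exp(lp[i])
  }
  inc
}

# split counting-process intervals into equal-length pieces no longer
# than `max_len` days (scalar or per-interval; covariates copied; `last`
# flags preserved on the final piece)
subdivide_intervals <- function(long, max_len) {
  if (all(!is.finite(max_len))) return(long)
  len <- long$tstop - long$tstart
  k <- pmax(1L, as.integer(ceiling(len / max_len)))
  if (all(k == 1L)) return(long)
  idx <- rep(seq_len(nrow(long)), k)
  out <- long[idx]
  piece <- unlist(lapply(k, seq_len), use.names = FALSE)
  a <- long$tstart[idx]; b <- long$tstop[idx]; kk <- k[idx]
  new_start <- a + (b - a) * (piece - 1) / kk
  new_stop <- ifelse(piece == kk, b, a + (b - a) * piece / kk)
  out[, "tstart" := new_start]
  out[, "tstop" := new_stop]
  out[, "last" := out$last & piece == kk]
  data.table::setorderv(out, c("row_id", "tstart"))
  out
}

# covariate-free per-country Nelson-Aalen cumulative hazard of one
# censoring cause, used as the stabilizer
marginal_cumhaz <- function(long, cause) {
  dd <- data.table::as.data.table(long)
  dd[, "mev" := as.integer(dd$last & !is.na(dd$censor_cause) &
                             dd$censor_cause == cause)]
  dd[, "cstratum" := factor(dd$country)]
  sf <- survival::survfit(
    survival::Surv(tstart, tstop, mev) ~ cstratum, data = dd, ctype = 1)
  nelson_aalen_table(sf, levels(dd$cstratum))
}
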