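# Validation machinery: time-truncated concordance with censoring
# correction, cluster-bootstrap score comparisons, absolute 90-day risk
# tables, and the Kaplan-Meier-at-first-score-reach check.

# censoring-survival G(t) used for pair weights: Kaplan-Meier of the
# combined censoring process (event indicator flipped), pooled over rows
censoring_km <- function(time, event) {
  sf <- survival::survfit(
    survival::Surv(time, 1 - event) ~ 1,
    data = data.frame(time = time, event = as.integer(event)))
  function(t) {
    idx <- findInterval(t, sf$time)
    c(1, sf$surv)[idx + 1L]
  }
}

# model-based censoring survival S_T * S_D per row at arbitrary times,
# covariates frozen at their cross-section values
model_G_matrix <- function(rows, model_T, model_D, times) {
  d <- as.data.frame(rows)
  lp_T <- censoring_lp(model_T, d)
  lp_D <- censoring_lp(model_D, d)
  out <- matrix(NA_real_, nrow(d), length(times))
  for (s in unique(d$country)) {
    i <- which(d$country == s)
    hT <- vapply(times, function(t) cumhaz_at(model_T$basehaz[[s]], t),
                 numeric(1L))
    hD <- vapply(times, function(t) cumhaz_at(model_D$basehaz[[s]], t),
                 numeric(1L))
    out[i, ] <- exp(-(outer(exp(lp_T[i]), hT) + outer(exp(lp_D[i]), hD)))
  }
  out
}

#' Time-truncated concordance index with censoring correction
#'
#' Inverse-probability-weighted concordance over pairs comparable within
#' the horizon: for every pair (i, j) with an observed event at
#' `t_i < min(t_j, horizon)`, concordance is credited when
#' `score_i > score_j` (half credit on score ties), with pair weight
#' `1 / (G_i(t_i) G_j(t_i))` where `G` is the censoring-survival
#' estimator — by default the Kaplan-Meier of the pooled censoring
#' process (so `G_i = G_j = G`), optionally the model-based product
#' `S_T * S_D` given each row's cross-section covariates, which corrects
#' for censoring that depends on prognosis.
#'
#' @param rows analysis rows with `time_days` and `event` (and the
#'   biomarker columns when `scores` is a [meld_definition()]).
#' @param scores numeric risk scores per row, or a [meld_definition()]
#'   evaluated on the rows' biomarkers.
#' @param horizon_days truncation horizon (default 90).
#' @param censoring_correction `"km"` (default), `"none"` (all pair
#'   weights 1), or `"model"` (requires `model_T` and `model_D`).
#' @param model_T,model_D [fit_censoring_model()] fits for
#'   `censoring_correction = "model"`.
#' @param n_boot optional number of patient-level bootstrap replicates
#'   for a standard error (0 = none).
#' @param seed bootstrap seed.
#' @return object of class `cindex_result`: `estimate`,
#'   `n_comparable_pairs`, `horizon_days`, and `bootstrap_se` when
#'   requested.
#' @export
truncated_cindex <- function(rows, scores, horizon_days = 90L,
                             censoring_correction = c("km", "none",
                                                      "model"),
                             model_T = NULL, model_D = NULL,
                             n_boot = 0L, seed = 1L) {
  censoring_correction <- match.arg(censoring_correction)
  d <- as.data.frame(rows)
  if (inherits(scores, "meld_definition"))
    scores <- meld_score(scores, d$creatinine, d$bilirubin, d$inr,
                         d$dialysis == 1L)
  stopifnot(length(scores) == nrow(d), all(is.finite(scores)),
            horizon_days > 0)
  est <- cindex_core(d$time_days, as.integer(d$event), scores,
                     horizon_days, censoring_correction,
                     if (censoring_correction == "model")
                       model_G_matrix(d, model_T, model_D,
                                      sort(unique(d$time_days)))
                     else NULL,
                     sort(unique(d$time_days)))
  res <- list(estimate = est$c, n_comparable_pairs = est$pairs,
              horizon_days = horizon_days,
              censoring_correction = censoring_correction)
  if (n_boot > 0L) {
    rng <- make_rng(seed)
    ids <- unique(d$patient_id)
    reps <- vapply(seq_len(n_boot), function(b) {
      take <- rng$sample(ids, length(ids), replace = TRUE)
      idx <- unlist(lapply(take, function(p) which(d$patient_id == p)))
      db <- d[idx, ]
      sb <- scores[idx]
      cindex_core(db$time_days, as.integer(db$event), sb, horizon_days,
                  censoring_correction,
                  if (censoring_correction == "model")
                    model_G_matrix(db, model_T, model_D,
                                   sort(unique(db$time_days)))
                  else NULL,
                  sort(unique(db$time_days)))$c
    }, numeric(1L))
    res$bootstrap_se <- stats::sd(reps)
  }
  class(res) <- "cindex_result"
  res
}

#' @export
print.cindex_result <- function(x, ...) {
  cat("Truncated c-index at ", x$horizon_days, " days: ",
      format(round(x$estimate, 4)), sep = "")
  if (!is.null(x$bootstrap_se))
    cat(" (bootstrap SE ", format(round(x$bootstrap_se, 4)), ")",
        sep = "")
  cat("\n", x$n_comparable_pairs, " comparable pairs, censoring ",
      "correction: ", x$censoring_correction, "\n", sep = "")
  invisible(x)
}

# core estimator; Gmat (rows x times) only for "model".  For the "km"
# and "none" corrections the pair weight depends on the pair only through
# the event time, so pairs can be counted with a Fenwick tree over score
# ranks in O(n log n); the model-based correction has per-subject weights
# and falls back to the O(events x n) double loop.
cindex_core <- function(time, event, score, horizon, correction,
                        Gmat, times) {
  n <- length(time)
  ev_any <- any(event == 1L & time < horizon)
  if (!ev_any) stop("no comparable pairs within the horizon")
  if (correction == "model") {
    ev_idx <- which(event == 1L & time < horizon)
    num <- den <- 0
    npairs <- 0
    for (i in ev_idx) {
      ti <- time[i]
      comp <- which(time > ti)
      if (!length(comp)) next
      col <- match(ti, times)
      wi <- 1 / (Gmat[i, col] * Gmat[comp, col])
      conc <- (score[i] > score[comp]) + 0.5 * (score[i] == score[comp])
      num <- num + sum(wi * conc)
      den <- den + sum(wi)
      npairs <- npairs + length(comp)
    }
    if (den == 0) stop("no comparable pairs within the horizon")
    return(list(c = num / den, pairs = npairs))
  }
  G <- if (correction == "km") censoring_km(time, event) else NULL
  rk <- match(score, sort(unique(score)))
  K <- max(rk)
  tree <- numeric(K)
  in_tree <- 0L
  bit_add <- function(r) {
    while (r <= K) {
      tree[r] <<- tree[r] + 1
      r <- r + bitwAnd(r, -r)
    }
  }
  bit_sum <- function(r) { # count of ranks <= r in the tree
    s <- 0
    while (r > 0L) {
      s <- s + tree[r]
      r <- r - bitwAnd(r, -r)
    }
    s
  }
  num <- den <- 0
  npairs <- 0
  # descending unique times: events at t are scored against the tree
  # (subjects with time > t), then the time-t subjects are inserted
  by_time <- split(seq_len(n), time)
  for (g in rev(seq_along(by_time))) {
    idx <- by_time[[g]]
    t_g <- time[idx[1L]]
    if (in_tree > 0L && t_g < horizon) {
      evs <- idx[event[idx] == 1L]
      if (length(evs)) {
        w <- if (is.null(G)) 1 else { gg <- G(t_g); 1 / (gg * gg) }
        for (i in evs) {
          less <- if (rk[i] > 1L) bit_sum(rk[i] - 1L) else 0
          eq <- bit_sum(rk[i]) - less
          num <- num + w * (less + 0.5 * eq)
          den <- den + w * in_tree
          npairs <- npairs + in_tree
        }
      }
    }
    for (i in idx) bit_add(rk[i])
    in_tree <- in_tree + length(idx)
  }
  if (den == 0) stop("no comparable pairs within the horizon")
  list(c = num / den, pairs = npairs)
}

#' Cluster-bootstrap comparison of two scores' c-indices
#'
#' Resamples patients with replacement (all rows of a patient move
#' together), recomputes both truncated c-indices per replicate, and
#' tests `delta = c_A - c_B` with a normal approximation on
#' `delta / SE(delta)`.
#'
#' @param rows analysis rows (with biomarker columns and `patient_id`).
#' @param score_A,score_B [meld_definition()] objects to compare.
#' @param n_boot bootstrap replicates (>= 2).
#' @param seed bootstrap seed.
#' @param horizon_days truncation horizon.
#' @param censoring_correction passed to [truncated_cindex()].
#' @return list `(c_A, c_B, delta, se, p_value, n_boot)`.
#' @export
bootstrap_compare <- function(rows, score_A, score_B, n_boot = 200L,
                              seed = 1L, horizon_days = 90L,
                              censoring_correction = "km") {
  if (n_boot < 2L) stop("n_boot must be at least 2")
  d <- as.data.frame(rows)
  sA <- meld_score(score_A, d$creatinine, d$bilirubin, d$inr,
                   d$dialysis == 1L)
  sB <- meld_score(score_B, d$creatinine, d$bilirubin, d$inr,
                   d$dialysis == 1L)
  times <- sort(unique(d$time_days))
  cA <- cindex_core(d$time_days, as.integer(d$event), sA, horizon_days,
                    censoring_correction, NULL, times)$c
  cB <- cindex_core(d$time_days, as.integer(d$event), sB, horizon_days,
                    censoring_correction, NULL, times)$c
  rng <- make_rng(seed)
  ids <- unique(d$patient_id)
  row_of <- split(seq_len(nrow(d)), d$patient_id)
  deltas <- vapply(seq_len(n_boot), function(b) {
    take <- rng$sample(ids, length(ids), replace = TRUE)
    idx <- unlist(row_of[take], use.names = FALSE)
    db_t <- d$time_days[idx]; db_e <- as.integer(d$event[idx])
    tms <- sort(unique(db_t))
    cindex_core(db_t, db_e, sA[idx], horizon_days,
                censoring_correction, NULL, tms)$c -
      cindex_core(db_t, db_e, sB[idx], horizon_days,
                  censoring_correction, NULL, tms)$c
  }, numeric(1L))
  se <- stats::sd(deltas)
  delta <- cA - cB
  p <- if (se == 0) {
    if (abs(delta) < 1e-15) 1 else 0
  } else 2 * stats::pnorm(-abs(delta) / se)
  list(c_A = cA, c_B = cB, delta = delta, se = se, p_value = p,
       n_boot = n_boot)
}

#' Deduplicate cross-section rows to first-appearance of each report
#'
#' Keeps, for each distinct reported biomarker set of a patient (the
#' exact tuple creatinine, bilirubin, INR, dialysis, report date), only
#' the first cross-section at which that patient was active — the
#' dependence-breaking rule used for absolute risk estimation.
#'
#' @param rows cross-section analysis rows.
#' @return the deduplicated rows.
#' @export
dedup_first_cross_section <- function(rows) {
  d <- as.data.frame(rows)
  key <- paste(d$patient_id, d$creatinine, d$bilirubin, d$inr,
               d$dialysis, d$report_date)
  ord <- order(d$cs_date)
  keep <- ord[!duplicated(key[ord])]
  out <- d[sort(keep), ]
  class(out) <- class(rows)
  out
}

#' Absolute 90-day mortality risk per integer score
#'
#' Fits a proportional-hazards model with the rounded integer score as
#' the single covariate on deduplicated cross-section rows (IPCW-weighted
#' when weighted rows are supplied) and converts the Breslow baseline to
#' per-score risks `1 - S0(h)^exp(beta s)`.  Confidence intervals by
#' patient-level cluster bootstrap.
#'
#' @param rows deduplicated rows ([dedup_first_cross_section()]); plain
#'   `cs_rows` for the unweighted fit or `ipcw_rows` for the weighted
#'   one.
#' @param definition the [meld_definition()] whose integer score is
#'   tabulated.
#' @param score_range integer scores to tabulate.
#' @param horizon_days risk horizon (default 90).
#' @param n_boot bootstrap replicates for CIs (0 = point estimates only).
#' @param seed bootstrap seed.
#' @return data.frame of class `risk_table`: `score`, `risk`, `ci_low`,
#'   `ci_high`, `extrapolated` (score outside the observed range).
#' @export
absolute_risk_table <- function(rows, definition, score_range = 20:40,
                                horizon_days = 90L, n_boot = 0L,
                                seed = 1L) {
  d <- as.data.frame(rows)
  weighted <- inherits(rows, "ipcw_rows")
  d$int_score <- round(meld_score(definition, d$creatinine, d$bilirubin,
                                  d$inr, d$dialysis == 1L))
  risk_of <- function(dd) {
    if (weighted) {
      fit <- survival::coxph(
        survival::Surv(tstart, tstop, ev) ~ int_score,
        data = dd, weights = dd$weight, ties = "efron")
    } else {
      fit <- survival::coxph(
        survival::Surv(time_days, event) ~ int_score,
        data = dd, ties = "efron")
    }
    bh <- survival::basehaz(fit, centered = FALSE)
    H0 <- cumhaz_at(bh[, c("time", "hazard")], horizon_days)
    1 - exp(-H0 * exp(stats::coef(fit) * score_range))
  }
  risk <- risk_of(d)
  out <- data.frame(score = score_range, risk = risk,
                    ci_low = NA_real_, ci_high = NA_real_,
                    extrapolated = score_range < min(d$int_score) |
                      score_range > max(d$int_score))
  if (n_boot > 0L) {
    rng <- make_rng(seed)
    ids <- unique(d$patient_id)
    row_of <- split(seq_len(nrow(d)), d$patient_id)
    reps <- vapply(seq_len(n_boot), function(b) {
      take <- rng$sample(ids, length(ids), replace = TRUE)
      risk_of(d[unlist(row_of[take], use.names = FALSE), ])
    }, numeric(length(score_range)))
    out$ci_low <- apply(reps, 1L, stats::quantile, 0.025)
    out$ci_high <- apply(reps, 1L, stats::quantile, 0.975)
  }
  class(out) <- c("risk_table", "data.frame")
  out
}

#' Kaplan-Meier 90-day risk at first reach of each score
#'
#' For each integer score `s`, takes each patient's first report at which
#' the rounded score equals `s` while the registration is active, follows
#' 90 days from that date, and estimates the Kaplan-Meier mortality —
#' a proportional-hazards-free check on [absolute_risk_table()]; each
#' patient contributes at most one observation per score stratum.
#'
#' @param x a validated [registry()].
#' @param definition the score to stratify on.
#' @param score_range integer scores.
#' @param horizon_days risk horizon.
#' @param min_patients strata with fewer patients are omitted.
#' @return data.frame of class `risk_table` (`n` = stratum size).
#' @export
km_first_reach <- function(x, definition, score_range = 20:40,
                           horizon_days = 90L, min_patients = 2L) {
  stopifnot(inherits(x, "registry"))
  reps <- data.table::as.data.table(x$reports)
  regs <- data.table::as.data.table(x$registrations)
  reps[, "int_score" := round(meld_score(
    definition, reps$creatinine, reps$bilirubin, reps$inr,
    reps$dialysis == 1L))]
  merged <- merge(reps, regs, by = "patient_id",
                  allow.cartesian = TRUE)
  exit_eff <- merged$exit_date
  exit_eff[is.na(exit_eff)] <- x$cutoff
  act <- merged$report_date >= merged$registration_date &
    merged$report_date < exit_eff
  merged <- merged[act]
  rows <- list()
  for (s in score_range) {
    sub <- merged[merged$int_score == s]
    if (nrow(sub) == 0L) next
    data.table::setorderv(sub, c("patient_id", "report_date"))
    sub <- sub[!duplicated(sub$patient_id)]
    if (nrow(sub) < min_patients) next
    oc <- encode_outcome_vec(sub$exit_date, sub$exit_reason,
                             sub$post_delisting_death_date,
                             sub$report_date, as.integer(horizon_days),
                             x$cutoff)
    keep <- oc$time_days > 0L
    if (sum(keep) < min_patients) next
    sf <- survival::survfit(
      survival::Surv(time, ev) ~ 1,
      data = data.frame(time = oc$time_days[keep],
                        ev = as.integer(oc$event[keep])))
    surv_h <- summary(sf, times = horizon_days, extend = TRUE)$surv
    rows[[length(rows) + 1L]] <- data.frame(
      score = s, risk = 1 - surv_h, ci_low = NA_real_,
      ci_high = NA_real_, n = sum(keep))
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(score = integer(), risk = numeric(),
                         ci_low = numeric(), ci_high = numeric(),
                         n = integer())
  class(out) <- c("risk_table", "data.frame")
  out
}
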