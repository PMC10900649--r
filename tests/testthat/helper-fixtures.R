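# Fixtures and independent oracles, all built in code.

# small hand-crafted registry with every outcome type
toy_registry <- function() {
  regs <- data.frame(
    patient_id = c("p1", "p2", "p3", "p4", "p5"),
    center_id = c("DEC1", "DEC1", "DEC2", "NLC1", "NLC1"),
    country = c("DE", "DE", "DE", "NL", "NL"),
    registration_date = as.Date(c("2014-01-10", "2014-01-05",
                                  "2014-01-01", "2014-02-01",
                                  "2014-03-01")),
    exit_date = as.Date(c("2014-03-01", "2014-04-01", "2014-02-10",
                          "2014-03-01", NA)),
    exit_reason = c("death", "transplant", "delisting", "delisting",
                    "censored"),
    post_delisting_death_date = as.Date(c(NA, NA, "2014-03-10", NA, NA)),
    post_delisting_followup_days = c(NA, NA, 28L, 90L, NA))
  reps <- data.frame(
    patient_id = c("p1", "p1", "p2", "p3", "p4", "p5"),
    report_date = as.Date(c("2014-01-10", "2014-02-01", "2014-01-05",
                            "2014-01-01", "2014-02-01", "2014-03-01")),
    creatinine = c(1.2, 1.5, 0.9, 2.4, 1.0, 1.1),
    bilirubin = c(2.0, 3.5, 1.2, 8.0, 1.5, 1.0),
    inr = c(1.1, 1.3, 1.0, 1.9, 1.2, 1.0),
    dialysis = c(0L, 0L, 0L, 0L, 0L, 0L))
  statuses <- data.frame(
    patient_id = "p2",
    start_date = as.Date("2014-01-08"),
    end_date = as.Date("2014-02-01"),
    status = "NT")
  registry(regs, reps, statuses, cutoff = as.Date("2014-06-30"))
}

# brute-force day-scan membership oracle for the cross-section dataset,
# built only from the exported scalar operations
cs_oracle <- function(x, dates, horizon = 90L) {
  out <- NULL
  regs <- as.data.frame(x$registrations)
  reps <- as.data.frame(x$reports)
  for (i in seq_len(nrow(regs))) {
    r <- regs[i, ]
    prep <- reps[reps$patient_id == r$patient_id, ]
    prep <- prep[order(prep$report_date), ]
    for (d in as.list(dates)) {
      if (!active_at(r, x$statuses, d, cutoff = x$cutoff)) next
      rep_d <- last_report_before(prep, d)
      if (is.null(rep_d)) next
      oc <- encode_outcome(r, d, horizon, cutoff = x$cutoff)
      if (oc$time_days <= 0) next
      out <- rbind(out, data.frame(
        patient_id = r$patient_id, cs_date = d,
        creatinine = rep_d$creatinine, time_days = oc$time_days,
        event = oc$event,
        censor_cause = if (is.na(oc$censor_cause)) NA_character_
                       else oc$censor_cause))
    }
  }
  out
}

# negative weighted stratified Breslow log partial likelihood for
# counting-process data (equals Efron when event times are distinct)
ncox_loglik <- function(beta, tstart, tstop, ev, X, w, strata) {
  lp <- as.vector(X %*% beta)
  ll <- 0
  for (s in unique(strata)) {
    i <- which(strata == s)
    for (j in i[ev[i] == 1]) {
      t <- tstop[j]
      risk <- i[tstart[i] < t & tstop[i] >= t]
      ll <- ll + w[j] * (lp[j] - log(sum(w[risk] * exp(lp[risk]))))
    }
  }
  -ll
}

# 30-row survival fixture with distinct event times and a biomarker mix
cox_fixture <- function(seed = 7, n = 30L) {
  set.seed(seed)
  d <- data.frame(
    patient_id = sprintf("q%02d", seq_len(n)),
    country = rep(c("DE", "NL"), length.out = n),
    creatinine = exp(rnorm(n, 0, 0.4)),
    bilirubin = exp(rnorm(n, 0.7, 0.8)),
    inr = exp(rnorm(n, 0.3, 0.3)),
    dialysis = as.integer(runif(n) < 0.2))
  d$stratum <- d$country
  lp <- 1.5 * log(ifelse(d$dialysis == 1L, 1, d$creatinine)) +
    0.8 * log(d$bilirubin) + 1.2 * log(d$inr) + 1.0 * d$dialysis
  tdeath <- rexp(n, 0.01 * exp(lp))
  tcens <- runif(n, 5, 120)
  d$time_days <- pmin(tdeath, tcens, 90)
  d$event <- tdeath <= pmin(tcens, 90)
  d$censor_cause <- ifelse(d$event, NA, "horizon")
  # jitter to keep event times distinct (Breslow == Efron)
  d$time_days <- d$time_days + seq_len(n) * 1e-4
  class(d) <- c("cs_rows", "data.frame")
  d
}

# hand-rolled product-limit estimator of the censoring survival G(t)
# (censoring = the complement of the event indicator), right-continuous
km_censoring_oracle <- function(time, event) {
  ut <- sort(unique(time))
  surv <- numeric(length(ut))
  g <- 1
  for (k in seq_along(ut)) {
    u <- ut[k]
    at_risk <- sum(time >= u)
    d <- sum(time == u & event == 0L)
    if (at_risk > 0) g <- g * (1 - d / at_risk)
    surv[k] <- g
  }
  function(t) {
    idx <- findInterval(t, ut)
    c(1, surv)[idx + 1L]
  }
}

# O(n^2) oracle for the truncated IPW concordance
cindex_oracle <- function(time, event, score, horizon,
                          correction = "km") {
  G <- if (correction == "km") km_censoring_oracle(time, event)
       else function(t) 1
  num <- den <- 0
  for (i in seq_along(time)) {
    if (event[i] != 1L || time[i] >= horizon) next
    for (j in seq_along(time)) {
      if (time[j] <= time[i]) next
      w <- 1 / G(time[i])^2
      conc <- if (score[i] > score[j]) 1
              else if (score[i] == score[j]) 0.5 else 0
      num <- num + w * conc
      den <- den + w
    }
  }
  num / den
}

# generic evaluation rows: lognormal biomarkers, survival driven by an
# independent linear predictor, exponential censoring
eval_rows <- function(n = 120, seed = 23, cens_rate = 0.008) {
  set.seed(seed)
  lp <- rnorm(n)
  tdeath <- rexp(n, 0.01 * exp(lp))
  tcens <- rexp(n, cens_rate)
  d <- data.frame(
    patient_id = sprintf("v%04d", seq_len(n)), country = "XX",
    stratum = "XX",
    creatinine = exp(rnorm(n, 0, 0.3)),
    bilirubin = exp(rnorm(n, 0.7, 0.7)),
    inr = exp(rnorm(n, 0.3, 0.3)), dialysis = 0L,
    time_days = ceiling(pmin(tdeath, tcens, 120)),
    event = tdeath <= pmin(tcens, 120))
  d$censor_cause <- ifelse(d$event, NA, "horizon")
  d$lp <- lp
  class(d) <- c("cs_rows", "data.frame")
  d
}

# small simulated registry cached per test run
small_sim <- local({
  cache <- new.env()
  function(scenario = "A_independent", n = 400L, seed = 5L) {
    key <- paste(scenario, n, seed)
    if (is.null(cache[[key]])) {
      cfg <- default_scenarios(n_patients = n, seed = seed)[[scenario]]
      cache[[key]] <- simulate_registry(cfg)
    }
    cache[[key]]
  }
})

weekly_grid <- function() {
  cross_section_dates(as.Date("2014-01-01"), as.Date("2015-12-30"), 7L)
}
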