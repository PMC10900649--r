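# Construction of the two 90-day time-stopped analysis designs:
# "from registration" (one row per listing, time origin = listing date)
# and "from cross-section" (one row per active patient per pre-specified
# calendar date, time origin = the cross-section date).

#' Calendar-time cross-section grid
#'
#' Arithmetic sequence of calendar dates `start, start + spacing, ...`, not
#' exceeding `end`.  The default weekly grid over 2006-12-31 to 2019-12-22
#' includes both endpoints because they are an exact multiple of 7 days
#' apart.
#'
#' @param start,end Dates, `start <= end`.
#' @param spacing_days positive integer spacing.
#' @return vector of Dates.
#' @export
cross_section_dates <- function(start = as.Date("2006-12-31"),
                                end = as.Date("2019-12-22"),
                                spacing_days = 7L) {
  start <- as.Date(start); end <- as.Date(end)
  if (spacing_days <= 0) stop("spacing_days must be positive")
  if (start > end) stop("start must not exceed end")
  seq(start, end, by = spacing_days)
}

#' Is a registration active (and transplantable) on a date?
#'
#' Active means `registration_date <= date < exit_date` (exit replaced by
#' the data cutoff while still listed; the exit day itself does not count)
#' and `date` not inside any of the patient's NT intervals
#' (`start_date <= date <= end_date`, open-ended intervals extend forever).
#'
#' @param registration one-row data.frame (or list) with
#'   `registration_date`, `exit_date`, `patient_id`.
#' @param statuses data.frame of NT intervals (may cover other patients).
#' @param date Date to probe.
#' @param cutoff administrative data cutoff.
#' @return logical.
#' @export
active_at <- function(registration, statuses, date,
                      cutoff = as.Date("2019-12-31")) {
  exit <- registration$exit_date
  if (is.na(exit)) exit <- cutoff
  if (!(registration$registration_date <= date && date < exit))
    return(FALSE)
  st <- statuses[statuses$patient_id == registration$patient_id, ,
                 drop = FALSE]
  if (nrow(st) == 0L) return(TRUE)
  ends <- st$end_date
  ends[is.na(ends)] <- as.Date("9999-12-31")
  !any(st$start_date <= date & date <= ends)
}

#' Last biomarker report on or before a date
#'
#' Returns the report with the greatest `report_date <= date` (inclusive:
#' allocation on a cross-section day uses the score reported that day), or
#' `NULL` if none.  Among same-day reports the last ingested wins.
#'
#' @param reports data.frame of one patient's reports, sorted by
#'   `report_date`.
#' @param date Date.
#' @param inclusive use `report_date <= date` (default) or strict `<`.
#' @return one-row data.frame, or `NULL`.
#' @export
last_report_before <- function(reports, date, inclusive = TRUE) {
  ok <- if (inclusive) reports$report_date <= date
        else reports$report_date < date
  if (!any(ok)) return(NULL)
  idx <- which(ok)
  latest <- idx[reports$report_date[idx] == max(reports$report_date[idx])]
  reports[latest[length(latest)], , drop = FALSE]
}

# Vectorized 90-day time-stopped outcome; the exported scalar wrapper is
# encode_outcome().  Delisted patients who die within `reclass_window`
# days of delisting count as waitlist deaths at their exit time.
encode_outcome_vec <- function(exit_date, exit_reason,
                               post_delisting_death_date,
                               origin_date, horizon_days, cutoff,
                               reclass_window = 90L) {
  n <- length(origin_date)
  exit_reason <- as.character(exit_reason)
  t_exit <- as.integer(exit_date - origin_date)
  t_cut <- as.integer(cutoff - origin_date)
  time <- rep.int(horizon_days, n)
  event <- rep.int(FALSE, n)
  cause <- rep.int("horizon", n)

  no_exit <- is.na(exit_date)
  adm <- no_exit & t_cut < horizon_days
  time[adm] <- t_cut[adm]
  cause[adm] <- "administrative"

  inwin <- !no_exit & t_exit <= horizon_days
  died <- inwin & exit_reason == "death"
  time[died] <- t_exit[died]; event[died] <- TRUE

  del <- inwin & exit_reason == "delisting"
  pd_days <- as.integer(post_delisting_death_date - exit_date)
  del_death <- del & !is.na(post_delisting_death_date) &
    pd_days <= reclass_window
  time[del_death] <- t_exit[del_death]; event[del_death] <- TRUE
  del_cens <- del & !del_death
  time[del_cens] <- t_exit[del_cens]; cause[del_cens] <- "delisting"

  tx <- inwin & exit_reason == "transplant"
  time[tx] <- t_exit[tx]; cause[tx] <- "transplant"

  # exits recorded as plain censoring (still-listed rows written with an
  # explicit "censored" exit at cutoff)
  cens <- inwin & exit_reason == "censored"
  time[cens] <- t_exit[cens]; cause[cens] <- "administrative"

  cause[event] <- NA_character_
  list(time_days = time, event = event, censor_cause = cause)
}

#' Encode the 90-day time-stopped outcome from an origin date
#'
#' Waitlist death within the horizon is an event; a delisted patient who
#' dies within 90 days of deregistration is treated as having died on
#' waitlist exit; transplantation and (other) delisting censor at exit;
#' follow-up past the horizon is truncated there; the data cutoff censors
#' administratively.
#'
#' @param registration one-row data.frame (or list) with `exit_date`,
#'   `exit_reason`, `post_delisting_death_date`.
#' @param origin_date Date, before the exit/cutoff.
#' @param horizon_days horizon (default 90).
#' @param cutoff administrative data cutoff.
#' @return list `(time_days, event, censor_cause)`; `censor_cause` is `NA`
#'   for events, else one of "transplant", "delisting", "administrative",
#'   "horizon".
#' @export
encode_outcome <- function(registration, origin_date, horizon_days = 90L,
                           cutoff = as.Date("2019-12-31")) {
  out <- encode_outcome_vec(
    as.Date(registration$exit_date), registration$exit_reason,
    as.Date(registration$post_delisting_death_date),
    as.Date(origin_date), as.integer(horizon_days), as.Date(cutoff))
  lapply(out, `[`, 1L)
}

# active (registration x date) pairs as a data.table; shared by the two
# dataset builders
active_pairs <- function(x, dates) {
  regs <- data.table::copy(x$registrations)
  regs[, "reg_id" := seq_len(nrow(regs))]
  regs[, "exit_eff" := {
    e <- regs$exit_date; e[is.na(e)] <- x$cutoff; e
  }]
  grid <- regs[, {
    ok <- dates >= .SD$registration_date & dates < .SD$exit_eff
    list(cs_date = dates[ok])
  }, by = c("reg_id"), .SDcols = c("registration_date", "exit_eff")]
  out <- merge(grid, regs, by = "reg_id", allow.cartesian = TRUE)
  # drop NT dates
  if (nrow(x$statuses)) {
    st <- data.table::as.data.table(x$statuses)
    st[, "end_eff" := {
      e <- st$end_date; e[is.na(e)] <- as.Date("9999-12-31"); e
    }]
    nt <- merge(out[, c("patient_id", "cs_date")], st,
                by = "patient_id", allow.cartesian = TRUE)
    nt <- nt[nt$start_date <= nt$cs_date & nt$cs_date <= nt$end_eff]
    if (nrow(nt)) {
      nt_key <- unique(paste(nt$patient_id, nt$cs_date))
      out <- out[!(paste(out$patient_id, out$cs_date) %in% nt_key)]
    }
  }
  out
}

#' Build the "from cross-section" analysis dataset
#'
#' One row per (active registration x cross-section date) with a usable
#' prior biomarker report.  Each row carries the last reported biomarkers
#' on or before the cross-section date, the report age, the 90-day
#' time-stopped outcome measured from the cross-section date, and the
#' stratum `country:cs_date`.  Patients waiting at several cross-sections
#' contribute several rows sharing `patient_id` (resample by patient).
#'
#' @param x a [registry()].
#' @param dates cross-section grid, e.g. [cross_section_dates()].
#' @param horizon_days outcome horizon (default 90).
#' @param inclusive_report use reports dated on the cross-section day
#'   itself (default TRUE).
#' @return data.frame of class `cs_rows` with columns `patient_id`,
#'   `center_id`, `country`, `cs_date`, `creatinine`, `bilirubin`, `inr`,
#'   `dialysis`, `report_date`, `report_age_days`, `time_days`, `event`,
#'   `censor_cause`, `stratum`.
#' @export
build_cross_section_dataset <- function(x, dates, horizon_days = 90L,
                                        inclusive_report = TRUE) {
  stopifnot(inherits(x, "registry"))
  dates <- sort(as.Date(dates))
  out <- active_pairs(x, dates)
  if (nrow(out) == 0L)
    return(empty_cs_rows())
  # last report on/before (or strictly before) each cs_date: rolling join
  rr <- data.table::copy(x$reports)
  rr[, "report_date_actual" := rr$report_date]
  if (!inclusive_report)
    rr[, "report_date" := rr$report_date + 1L] # shift so roll excludes same day
  data.table::setkey(rr, patient_id, report_date)
  probe <- out[, c("patient_id", "cs_date")]
  data.table::setnames(probe, "cs_date", "report_date")
  got <- rr[probe, roll = Inf, on = c("patient_id", "report_date")]
  out[, c("creatinine", "bilirubin", "inr", "dialysis", "report_date") :=
        list(got$creatinine, got$bilirubin, got$inr,
             as.integer(got$dialysis), got$report_date_actual)]
  out <- out[!is.na(out$report_date)]
  oc <- encode_outcome_vec(out$exit_date, out$exit_reason,
                           out$post_delisting_death_date,
                           out$cs_date, as.integer(horizon_days), x$cutoff)
  out[, c("report_age_days", "time_days", "event", "censor_cause") :=
        list(as.integer(out$cs_date - out$report_date),
             oc$time_days, oc$event, oc$censor_cause)]
  out <- out[out$time_days > 0L]
  out[, "stratum" := paste(out$country, format(out$cs_date), sep = ":")]
  cols <- c("patient_id", "center_id", "country", "cs_date",
            "creatinine", "bilirubin", "inr", "dialysis", "report_date",
            "report_age_days", "time_days", "event", "censor_cause",
            "stratum")
  res <- as.data.frame(out[, cols, with = FALSE])
  class(res) <- c("cs_rows", "data.frame")
  attr(res, "design") <- "cross_section"
  attr(res, "horizon_days") <- as.integer(horizon_days)
  res
}

empty_cs_rows <- function() {
  res <- data.frame(
    patient_id = character(), center_id = character(),
    country = character(), cs_date = as.Date(character()),
    creatinine = numeric(), bilirubin = numeric(), inr = numeric(),
    dialysis = integer(), report_date = as.Date(character()),
    report_age_days = integer(), time_days = integer(),
    event = logical(), censor_cause = character(), stratum = character())
  class(res) <- c("cs_rows", "data.frame")
  res
}

#' Build the "from registration" analysis dataset
#'
#' One row per listing episode: time origin is the registration date,
#' biomarkers are the registration-time report, stratum is the country.
#' Registrations without a report on the registration day (more precisely,
#' none on/before it — registration-time reporting is mandatory) are
#' excluded; their count is attached as attribute `n_dropped_no_report`.
#'
#' @inheritParams build_cross_section_dataset
#' @return data.frame of class `cs_rows` (with `cs_date` equal to the
#'   registration date).
#' @export
build_from_registration_dataset <- function(x, horizon_days = 90L) {
  stopifnot(inherits(x, "registry"))
  regs <- data.table::copy(x$registrations)
  rr <- data.table::copy(x$reports)
  rr[, "report_date_actual" := rr$report_date]
  data.table::setkey(rr, patient_id, report_date)
  probe <- regs[, c("patient_id", "registration_date")]
  data.table::setnames(probe, "registration_date", "report_date")
  got <- rr[probe, roll = Inf, on = c("patient_id", "report_date")]
  has_rep <- !is.na(got$report_date_actual)
  n_dropped <- sum(!has_rep)
  if (n_dropped)
    warning(n_dropped, " registration(s) without a registration-time ",
            "report were dropped")
  out <- regs[has_rep]
  got <- got[has_rep]
  oc <- encode_outcome_vec(out$exit_date, out$exit_reason,
                           out$post_delisting_death_date,
                           out$registration_date,
                           as.integer(horizon_days), x$cutoff)
  res <- data.frame(
    patient_id = out$patient_id, center_id = out$center_id,
    country = out$country, cs_date = out$registration_date,
    creatinine = got$creatinine, bilirubin = got$bilirubin,
    inr = got$inr, dialysis = as.integer(got$dialysis),
    report_date = got$report_date_actual,
    report_age_days = as.integer(out$registration_date -
                                   got$report_date_actual),
    time_days = oc$time_days, event = oc$event,
    censor_cause = oc$censor_cause, stratum = out$country)
  res <- res[res$time_days > 0L, ]
  class(res) <- c("cs_rows", "data.frame")
  attr(res, "design") <- "from_registration"
  attr(res, "horizon_days") <- as.integer(horizon_days)
  attr(res, "n_dropped_no_report") <- n_dropped
  res
}
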