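test_that("the weekly calendar grid matches the day-count arithmetic", {
  start <- as.Date("2006-12-31"); end <- as.Date("2019-12-22")
  g <- cross_section_dates(start, end, 7)
  expect_equal(g[1], start)
  expect_equal(g[length(g)], end)  # endpoints an exact multiple of 7 apart
  expect_length(g, as.integer(end - start) / 7 + 1)
  expect_equal(cross_section_dates(start, start, 7), start)
  expect_error(cross_section_dates(start, end, 0), "positive")
})

test_that("activity respects the half-open listing interval and NT periods", {
  x <- toy_registry()
  regs <- as.data.frame(x$registrations)
  p1 <- regs[regs$patient_id == "p1", ]
  p2 <- regs[regs$patient_id == "p2", ]
  expect_true(active_at(p1, x$statuses, as.Date("2014-01-15"),
                        x$cutoff))
  expect_false(active_at(p1, x$statuses, as.Date("2014-01-09"),
                         x$cutoff))
  expect_false(active_at(p1, x$statuses, p1$exit_date, x$cutoff))
  # p2 is NT between Jan 8 and Feb 1
  expect_false(active_at(p2, x$statuses, as.Date("2014-01-10"),
                         x$cutoff))
  expect_true(active_at(p2, x$statuses, as.Date("2014-02-02"),
                        x$cutoff))
})

test_that("the last report on or before a date is selected, stably", {
  reps <- data.frame(
    patient_id = "p", report_date = as.Date("2014-01-01") + c(0, 20),
    creatinine = c(1.0, 2.0), bilirubin = 1, inr = 1, dialysis = 0L)
  expect_equal(last_report_before(reps, as.Date("2014-01-26"))$creatinine,
               2.0)
  expect_equal(last_report_before(reps, as.Date("2014-01-11"))$creatinine,
               1.0)
  expect_null(last_report_before(reps, as.Date("2013-12-31")))
  # same-day duplicate: the later-ingested row wins
  dup <- rbind(reps, data.frame(patient_id = "p",
                                report_date = as.Date("2014-01-21"),
                                creatinine = 3.0, bilirubin = 1,
                                inr = 1, dialysis = 0L))
  expect_equal(last_report_before(dup, as.Date("2014-01-21"))$creatinine,
               3.0)
})

test_that("outcomes are 90-day time-stopped with delisting-death reclassification", {
  cutoff <- as.Date("2014-12-31")
  reg <- function(exit, reason, pdd = NA) {
    data.frame(exit_date = as.Date(exit), exit_reason = reason,
               post_delisting_death_date = as.Date(pdd))
  }
  origin <- as.Date("2014-01-01")
  # delisted day 40, dies 30 days later: a waitlist death at day 40
  oc <- encode_outcome(reg("2014-02-10", "delisting", "2014-03-12"),
                       origin, 90, cutoff)
  expect_equal(oc$time_days, 40L)
  expect_true(oc$event)
  # delisted day 40, no recorded death: censored at exit
  oc <- encode_outcome(reg("2014-02-10", "delisting"), origin, 90,
                       cutoff)
  expect_false(oc$event)
  expect_equal(oc$censor_cause, "delisting")
  # post-delisting death beyond the 90-day reclassification window
  oc <- encode_outcome(reg("2014-02-10", "delisting", "2014-06-10"),
                       origin, 90, cutoff)
  expect_false(oc$event)
  # transplanted day 20: censored
  oc <- encode_outcome(reg("2014-01-21", "transplant"), origin, 90,
                       cutoff)
  expect_equal(oc$time_days, 20L)
  expect_equal(oc$censor_cause, "transplant")
  # still listed at day 90: horizon truncation
  oc <- encode_outcome(reg(NA, "censored"), origin, 90, cutoff)
  expect_equal(oc$time_days, 90L)
  expect_equal(oc$censor_cause, "horizon")
  # data cutoff before the horizon
  oc <- encode_outcome(reg(NA, "censored"), as.Date("2014-12-01"), 90,
                       cutoff)
  expect_equal(oc$time_days, 30L)
  expect_equal(oc$censor_cause, "administrative")
  # death beyond the horizon is a horizon-censored row
  oc <- encode_outcome(reg("2014-06-01", "death"), origin, 90, cutoff)
  expect_equal(oc$time_days, 90L)
  expect_false(oc$event)
})

test_that("the cross-section builder matches the day-scan oracle", {
  x <- toy_registry()
  grid <- cross_section_dates(as.Date("2014-01-01"),
                              as.Date("2014-06-25"), 7)
  built <- build_cross_section_dataset(x, grid)
  oracle <- cs_oracle(x, grid)
  key <- function(d) sort(paste(d$patient_id, d$cs_date))
  expect_equal(key(built), key(oracle))
  m <- merge(built, oracle, by = c("patient_id", "cs_date"))
  expect_equal(m$time_days.x, m$time_days.y)
  expect_equal(m$event.x, m$event.y)
  expect_equal(m$creatinine.x, m$creatinine.y)

  # and on a 20-patient simulated registry
  sim <- small_sim("B_informative", n = 20, seed = 11)
  built <- build_cross_section_dataset(sim$registry, weekly_grid())
  oracle <- cs_oracle(sim$registry, weekly_grid())
  expect_equal(key(built), key(oracle))
  m <- merge(built, oracle, by = c("patient_id", "cs_date"))
  expect_equal(m$time_days.x, m$time_days.y)
  expect_equal(m$event.x, m$event.y)
})

test_that("no analysis row uses a report from after its cross-section", {
  sim <- small_sim("B_informative", n = 400, seed = 5)
  cs <- build_cross_section_dataset(sim$registry, weekly_grid())
  expect_true(all(cs$report_date <= cs$cs_date))
  expect_true(all(cs$time_days >= 1 & cs$time_days <= 90))
  expect_true(all(is.na(cs$censor_cause[cs$event])))
  expect_true(all(!is.na(cs$censor_cause[!cs$event])))
})

test_that("from-registration rows use listing reports, one per episode", {
  x <- toy_registry()
  fr <- build_from_registration_dataset(x)
  expect_equal(nrow(fr), 5L)
  expect_equal(fr$stratum, fr$country)
  # p3 delisted day 40, died 28 days post-delisting: reclassified death
  p3 <- fr[fr$patient_id == "p3", ]
  expect_true(p3$event)
  expect_equal(p3$time_days, 40L)
  # registration without a listing report is dropped with a warning
  regs <- as.data.frame(x$registrations)
  reps <- as.data.frame(x$reports)
  regs <- rbind(regs, within(regs[1, ], {
    patient_id <- "late"
    registration_date <- as.Date("2014-01-01")
    exit_date <- as.Date(NA); exit_reason <- "censored"
    post_delisting_death_date <- as.Date(NA)
  }))
  x2 <- registry(regs, reps, as.data.frame(x$statuses),
                 cutoff = x$cutoff)
  expect_warning(fr2 <- build_from_registration_dataset(x2),
                 "without a registration-time report")
  expect_equal(nrow(fr2), 5L)
})
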