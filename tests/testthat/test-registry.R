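test_that("registry CSV round-trip is the identity", {
  x <- toy_registry()
  dir <- withr::local_tempdir()
  paths <- write_registry(x, dir)
  y <- read_registry(paths[1], paths[2], paths[3],
                     cutoff = as.Date("2014-06-30"))
  expect_equal(as.data.frame(y$registrations),
               as.data.frame(x$registrations))
  expect_equal(as.data.frame(y$reports), as.data.frame(x$reports))
  expect_equal(as.data.frame(y$statuses), as.data.frame(x$statuses))
})

test_that("schema violations are reported by column name", {
  x <- toy_registry()
  dir <- withr::local_tempdir()
  paths <- write_registry(x, dir)
  bad <- read.csv(paths[2])
  names(bad)[names(bad) == "creatinine"] <- "creatinin"
  write.csv(bad, paths[2], row.names = FALSE)
  expect_error(read_registry(paths[1], paths[2], paths[3]),
               "creatinine")
})

test_that("unparseable dates point at the offending rows", {
  x <- toy_registry()
  dir <- withr::local_tempdir()
  paths <- write_registry(x, dir)
  bad <- read.csv(paths[2], colClasses = "character")
  bad$report_date[2] <- "not-a-date"
  write.csv(bad, paths[2], row.names = FALSE)
  expect_error(read_registry(paths[1], paths[2], paths[3]),
               "report_date.*row")
})

test_that("impossible biomarkers and missing reports are excluded with counts", {
  x <- toy_registry()
  # add 5 clean patients, one all-zero reporter, one without any report
  extra_regs <- data.frame(
    patient_id = c(sprintf("x%d", 1:5), "zero", "norep"),
    center_id = "DEC1", country = "DE",
    registration_date = as.Date("2014-01-02"),
    exit_date = as.Date(NA), exit_reason = "censored",
    post_delisting_death_date = as.Date(NA),
    post_delisting_followup_days = NA_integer_)
  extra_reps <- data.frame(
    patient_id = c(sprintf("x%d", 1:5), "zero"),
    report_date = as.Date("2014-01-02"),
    creatinine = c(rep(1, 5), 0), bilirubin = c(rep(1, 5), 0),
    inr = c(rep(1.1, 5), 0), dialysis = 0L)
  x2 <- registry(rbind(as.data.frame(x$registrations), extra_regs),
                 rbind(as.data.frame(x$reports), extra_reps),
                 as.data.frame(x$statuses),
                 cutoff = as.Date("2014-06-30"))
  v <- validate_registry(x2)
  expect_equal(nrow(v$registry$registrations), 10L)  # 12 in, 2 out
  expect_equal(v$exclusions$n[v$exclusions$reason ==
                                "impossible_biomarkers"], 1L)
  expect_equal(v$exclusions$n[v$exclusions$reason == "no_report"], 1L)
  expect_false("zero" %in% v$registry$registrations$patient_id)
  # all-positive reporters are retained
  expect_true(all(sprintf("x%d", 1:5) %in%
                    v$registry$registrations$patient_id))
})

test_that("center split assigns whole centers near the target share", {
  # one country, centers of size 70 and 30: the size-70 center must be
  # the development cohort
  regs <- data.frame(
    patient_id = sprintf("c%03d", 1:100),
    center_id = rep(c("A", "B"), c(70, 30)),
    country = "DE",
    registration_date = as.Date("2014-01-01"),
    exit_date = as.Date(NA), exit_reason = "censored",
    post_delisting_death_date = as.Date(NA),
    post_delisting_followup_days = NA_integer_)
  reps <- data.frame(patient_id = regs$patient_id,
                     report_date = as.Date("2014-01-01"),
                     creatinine = 1, bilirubin = 1, inr = 1.1,
                     dialysis = 0L)
  x <- registry(regs, reps, NULL)
  sp <- center_split(x, dev_fraction = 0.7, seed = 1)
  expect_setequal(unique(sp$development$registrations$center_id), "A")
  expect_setequal(unique(sp$validation$registrations$center_id), "B")
})

test_that("an extreme dev fraction greedily over-assigns to development", {
  regs <- data.frame(
    patient_id = sprintf("c%03d", 1:100),
    center_id = rep(c("A", "B"), each = 50),
    country = "DE",
    registration_date = as.Date("2014-01-01"),
    exit_date = as.Date(NA), exit_reason = "censored",
    post_delisting_death_date = as.Date(NA),
    post_delisting_followup_days = NA_integer_)
  reps <- data.frame(patient_id = regs$patient_id,
                     report_date = as.Date("2014-01-01"),
                     creatinine = 1, bilirubin = 1, inr = 1.1,
                     dialysis = 0L)
  x <- registry(regs, reps, NULL)
  sp <- center_split(x, dev_fraction = 0.999, seed = 1)
  # both assignments miss the target; the greedy rule picks the larger
  # development share (share 1.0 beats 0.5)
  expect_equal(nrow(sp$development$registrations), 100L)
})

test_that("single-center countries are split at random, reproducibly", {
  regs <- data.frame(
    patient_id = sprintf("h%03d", 1:100),
    center_id = "HU1", country = "HU",
    registration_date = as.Date("2014-01-01"),
    exit_date = as.Date(NA), exit_reason = "censored",
    post_delisting_death_date = as.Date(NA),
    post_delisting_followup_days = NA_integer_)
  reps <- data.frame(patient_id = regs$patient_id,
                     report_date = as.Date("2014-01-01"),
                     creatinine = 1, bilirubin = 1, inr = 1.1,
                     dialysis = 0L)
  x <- registry(regs, reps, NULL)
  expect_error(center_split(x, 0.7, seed = 2), "single center")
  s1 <- center_split(x, 0.7, single_center_countries = "HU", seed = 2)
  s2 <- center_split(x, 0.7, single_center_countries = "HU", seed = 2)
  n_dev <- nrow(s1$development$registrations)
  expect_equal(n_dev, nrow(s2$development$registrations))
  expect_identical(s1$assignment$cohort, s2$assignment$cohort)
  expect_gt(n_dev, 55)
  expect_lt(n_dev, 85)
})

test_that("the split is a partition and centers never straddle cohorts", {
  sim <- small_sim("B_informative", n = 400, seed = 5)
  x <- validate_registry(sim$registry)$registry
  sp <- center_split(x, 0.7, seed = 3)
  dev_ids <- sp$development$registrations$patient_id
  val_ids <- sp$validation$registrations$patient_id
  expect_length(intersect(dev_ids, val_ids), 0)
  expect_setequal(c(dev_ids, val_ids), x$registrations$patient_id)
  expect_length(intersect(unique(sp$development$registrations$center_id),
                          unique(sp$validation$registrations$center_id)),
                0)
})
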