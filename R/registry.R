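# Registry container and I/O.
#
# A registry is three tables mirroring how transplant waitlist registries
# are exported: one row per listing episode (registrations), one row per
# dated biomarker report, and one row per non-transplantable (NT) interval.

REGISTRATION_COLS <- c("patient_id", "center_id", "country",
                       "registration_date", "exit_date", "exit_reason",
                       "post_delisting_death_date",
                       "post_delisting_followup_days")
REPORT_COLS <- c("patient_id", "report_date", "creatinine", "bilirubin",
                 "inr", "dialysis")
STATUS_COLS <- c("patient_id", "start_date", "end_date", "status")
EXIT_REASONS <- c("death", "transplant", "delisting", "censored")

#' Construct a registry object
#'
#' Bundles the three registry tables into a single object with a data
#' cutoff (the administrative end of observation; registrations without an
#' exit are censored there).
#'
#' @param registrations data.frame, one row per listing episode; columns
#'   `patient_id`, `center_id`, `country`, `registration_date` (Date),
#'   `exit_date` (Date or NA while still listed), `exit_reason` (one of
#'   "death", "transplant", "delisting", "censored" or NA while listed),
#'   `post_delisting_death_date` (Date or NA),
#'   `post_delisting_followup_days` (integer or NA).
#' @param reports data.frame of biomarker reports: `patient_id`,
#'   `report_date` (Date), `creatinine`, `bilirubin`, `inr` (mg/dL, mg/dL,
#'   ratio), `dialysis` (0/1, biweekly dialysis).
#' @param statuses data.frame of NT intervals: `patient_id`, `start_date`,
#'   `end_date` (Date or NA for open-ended), `status` (fixed "NT").  May be
#'   empty.
#' @param cutoff Date; administrative data cutoff.
#' @return an object of class `registry`.
#' @export
registry <- function(registrations, reports, statuses = NULL,
                     cutoff = as.Date("2019-12-31")) {
  registrations <- data.table::as.data.table(registrations)
  reports <- data.table::as.data.table(reports)
  if (is.null(statuses) || nrow(statuses) == 0L) {
    statuses <- data.table::data.table(
      patient_id = character(), start_date = as.Date(character()),
      end_date = as.Date(character()), status = character())
  } else {
    statuses <- data.table::as.data.table(statuses)
  }
  bad <- !is.na(registrations$exit_date) &
    registrations$exit_date < registrations$registration_date
  if (any(bad))
    stop("exit_date before registration_date for patient(s): ",
         paste(utils::head(registrations$patient_id[bad], 5L), collapse = ", "))
  pdd <- registrations$post_delisting_death_date
  if (any(!is.na(pdd) & registrations$exit_reason != "delisting"))
    stop("post_delisting_death_date present for a non-delisting exit")
  if (any(!is.na(pdd) & pdd < registrations$exit_date))
    stop("post_delisting_death_date before exit_date")
  if (any(!is.na(statuses$end_date) &
            statuses$end_date < statuses$start_date))
    stop("NT interval with end_date before start_date")
  data.table::setkey(reports, patient_id, report_date)
  structure(list(registrations = registrations, reports = reports,
                 statuses = statuses, cutoff = as.Date(cutoff)),
            class = "registry")
}

#' @export
print.registry <- function(x, ...) {
  cat("Waitlist registry: ", nrow(x$registrations), " registrations (",
      length(unique(x$registrations$patient_id)), " patients), ",
      nrow(x$reports), " biomarker reports, ",
      nrow(x$statuses), " NT intervals\n", sep = "")
  cat("Data cutoff: ", format(x$cutoff), "\n", sep = "")
  invisible(x)
}

parse_date_col <- function(x, col, file) {
  if (inherits(x, "Date")) return(x)
  x <- as.character(x)
  out <- as.Date(x, format = "%Y-%m-%d")
  bad <- which(!is.na(x) & x != "" & is.na(out))
  if (length(bad))
    stop("unparseable date in column '", col, "' of ", file,
         " at row(s) ", paste(utils::head(bad, 5L), collapse = ", "))
  out
}

read_table_checked <- function(path, required, date_cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, colClasses = list(character = "patient_id"))
  missing <- setdiff(required, names(dt))
  if (length(missing))
    stop("file ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  for (col in date_cols)
    data.table::set(dt, j = col,
                    value = parse_date_col(dt[[col]], col, path))
  dt
}

#' Read a registry from CSV files
#'
#' Parses the three registry CSVs (ISO-8601 dates) and returns a
#' [registry()].  Rows are preserved in input order and no filtering is
#' applied; run [validate_registry()] afterwards.
#'
#' @param registrations_path,reports_path,statuses_path file paths;
#'   `statuses_path` may be `NULL` if there are no NT intervals.
#' @param cutoff administrative data cutoff (Date).
#' @return a [registry()].
#' @export
read_registry <- function(registrations_path, reports_path,
                          statuses_path = NULL,
                          cutoff = as.Date("2019-12-31")) {
  regs <- read_table_checked(
    registrations_path, REGISTRATION_COLS,
    c("registration_date", "exit_date", "post_delisting_death_date"))
  reps <- read_table_checked(reports_path, REPORT_COLS, "report_date")
  stat <- NULL
  if (!is.null(statuses_path))
    stat <- read_table_checked(statuses_path, STATUS_COLS,
                               c("start_date", "end_date"))
  registry(regs, reps, stat, cutoff = cutoff)
}

#' Write a registry to CSV files
#'
#' Inverse of [read_registry()]: writes `registrations.csv`, `reports.csv`
#' and `statuses.csv` under `dir`.
#'
#' @param x a [registry()].
#' @param dir output directory (created if needed).
#' @return invisibly, the three file paths.
#' @export
write_registry <- function(x, dir) {
  stopifnot(inherits(x, "registry"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("registrations.csv", "reports.csv",
                            "statuses.csv"))
  data.table::fwrite(x$registrations, paths[1L])
  data.table::fwrite(x$reports, paths[2L])
  data.table::fwrite(x$statuses, paths[3L])
  invisible(paths)
}

#' Validate a registry and apply exclusion rules
#'
#' Removes listing episodes that cannot enter analysis:
#' \itemize{
#'   \item `impossible_biomarkers` — the registration-time report (first
#'     report dated on or after the registration date) has any of
#'     creatinine, bilirubin, INR \eqn{\le} 0, e.g. the all-zero reporting
#'     artifact;
#'   \item `no_report` — no report dated on or after registration
#'     (registration-time reporting is mandatory).
#' }
#' Reports belonging to excluded registrations are dropped with them.
#'
#' @param x a [registry()].
#' @return list with elements `registry` (the filtered registry) and
#'   `exclusions` (data.frame of reason/count), of class
#'   `registry_validation`.
#' @export
validate_registry <- function(x) {
  stopifnot(inherits(x, "registry"))
  regs <- data.table::copy(x$registrations)
  reps <- x$reports
  # registration-time report: first report on/after the listing date
  # (rolling join, next-observation-carried-backward)
  rr <- data.table::copy(reps)
  rr[, "rep_date_actual" := rr$report_date]
  data.table::setkey(rr, patient_id, report_date)
  probe <- regs[, c("patient_id", "registration_date")]
  data.table::setnames(probe, "registration_date", "report_date")
  listed <- rr[probe, roll = -Inf,
               on = c("patient_id", "report_date")]
  no_report <- is.na(listed$rep_date_actual)
  impossible <- !no_report &
    (listed$creatinine <= 0 | listed$bilirubin <= 0 | listed$inr <= 0)
  drop <- no_report | impossible
  exclusions <- data.frame(
    reason = c("impossible_biomarkers", "no_report"),
    n = c(sum(impossible), sum(no_report)))
  keep_ids <- listed$patient_id[!drop]
  out <- registry(regs[regs$patient_id %in% keep_ids],
                  reps[reps$patient_id %in% keep_ids],
                  x$statuses[x$statuses$patient_id %in% keep_ids],
                  cutoff = x$cutoff)
  structure(list(registry = out, exclusions = exclusions),
            class = "registry_validation")
}

#' @export
print.registry_validation <- function(x, ...) {
  print(x$registry)
  cat("Exclusions:\n")
  print(x$exclusions, row.names = FALSE)
  invisible(x)
}

#' Split a registry into development and validation cohorts by center
#'
#' For countries with several centers, whole centers are assigned to one
#' cohort (enabling geographical validation): centers are taken largest
#' first (ties broken on `center_id`) and assigned to the development
#' cohort whenever that moves the country's development share closer to
#' `dev_fraction` (ties toward development).  For the listed single-center
#' countries, patients are assigned individually at random with probability
#' `dev_fraction`.
#'
#' @param x a [registry()].
#' @param dev_fraction target development share, in (0, 1); default 0.7.
#' @param single_center_countries character vector of country codes whose
#'   patients are split at random rather than by center.
#' @param seed integer seed for the random single-center splits.
#' @return list with `development` and `validation` registries and an
#'   `assignment` data.frame (patient_id, country, center_id, cohort).
#' @export
center_split <- function(x, dev_fraction = 0.7,
                         single_center_countries = character(), seed = 1L) {
  stopifnot(inherits(x, "registry"),
            dev_fraction > 0, dev_fraction < 1)
  regs <- x$registrations
  pats <- unique(as.data.frame(
    regs[, c("patient_id", "country", "center_id")]))
  assign <- character(nrow(pats))
  rng <- make_rng(seed)
  for (ctry in sort(unique(pats$country))) {
    idx <- which(pats$country == ctry)
    if (ctry %in% single_center_countries) {
      assign[idx] <- ifelse(rng$runif(length(idx)) < dev_fraction,
                            "development", "validation")
      next
    }
    centers <- sort(table(pats$center_id[idx]), decreasing = TRUE)
    # stable order: size desc, then center_id
    ord <- order(-as.integer(centers), names(centers))
    centers <- centers[ord]
    if (length(centers) == 1L)
      stop("country '", ctry, "' has a single center; list it in ",
           "'single_center_countries' to split its patients at random")
    n_ctry <- length(idx)
    dev_n <- 0L
    dev_centers <- character()
    for (k in seq_along(centers)) {
      cur <- abs(dev_n / n_ctry - dev_fraction)
      cand <- abs((dev_n + centers[k]) / n_ctry - dev_fraction)
      if (cand <= cur) {
        dev_centers <- c(dev_centers, names(centers)[k])
        dev_n <- dev_n + centers[k]
      }
    }
    assign[idx] <- ifelse(pats$center_id[idx] %in% dev_centers,
                          "development", "validation")
  }
  assignment <- data.frame(pats, cohort = assign)
  subset_registry <- function(ids) {
    registry(regs[regs$patient_id %in% ids],
             x$reports[x$reports$patient_id %in% ids],
             x$statuses[x$statuses$patient_id %in% ids],
             cutoff = x$cutoff)
  }
  list(development = subset_registry(
         assignment$patient_id[assignment$cohort == "development"]),
       validation = subset_registry(
         assignment$patient_id[assignment$cohort == "validation"]),
       assignment = assignment)
}

# Local RNG handle: runs draws under a private seed without touching the
# caller's .Random.seed.
make_rng <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    st <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
    st
  })
  with_state <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, globalenv())
    })
    expr
  }
  list(
    runif = function(n, ...) with_state(stats::runif(n, ...)),
    rnorm = function(n, ...) with_state(stats::rnorm(n, ...)),
    rbinom = function(n, ...) with_state(stats::rbinom(n, ...)),
    sample = function(...) with_state(sample(...)),
    sample_int = function(n, size, replace = FALSE, prob = NULL)
      with_state(sample.int(n, size, replace = replace, prob = prob)))
}
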