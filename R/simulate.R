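# Synthetic waitlist registry generator.
#
# The generator reproduces the statistical structure the cross-section /
# IPCW analysis relies on, with known ground truth:
#   * latent log-biomarkers follow a day-granular random walk, a
#     "progressor" subgroup drifting upward;
#   * reports are emitted at registration, whenever the current report's
#     age exceeds the recertification limit for the patient's reported
#     UNOS-MELD band (sicker patients recertify more often), and at random
#     voluntary updates;
#   * the death hazard on each day is log-linear in the currently
#     *reported* biomarkers (dialysis-substituted creatinine, bilirubin,
#     INR, dialysis flag);
#   * transplant and delisting hazards are either constant or log-linear
#     in the currently reported UNOS-MELD score, which makes censoring
#     informative while keeping a censoring model with time-varying
#     reported covariates correctly specified.

#' Simulation configuration
#'
#' @param n_patients number of patients.
#' @param window_start,window_end calendar window (also the data cutoff).
#' @param countries data.frame with columns `code`, `centers`, `share`.
#' @param true_beta named numeric: log hazard ratios for death per log-unit
#'   of reported creatinine (1.0 substituted under dialysis), bilirubin,
#'   INR, and for the dialysis indicator.
#' @param baseline_death_hazard events/day at the covariate reference.
#' @param transplant_model,delisting_model `"independent"` (constant
#'   hazard) or `"score_dependent"` (hazard `base * exp(gamma*(score-20))`
#'   in the currently reported UNOS-MELD score).
#' @param transplant_base,delisting_base hazard per day (at UNOS-MELD 20
#'   for score-dependent models).
#' @param gamma_tx,gamma_dl log hazard ratio per UNOS-MELD point.
#' @param biomarker_volatility per-day s.d. of the latent log-biomarker
#'   random walk (creatinine, bilirubin, INR) at the reference severity
#'   (UNOS-MELD 20).
#' @param volatility_severity log-multiplier on the volatility per
#'   UNOS-MELD point of the current latent severity: sicker patients'
#'   biomarkers are more labile (`sd * exp(vs * (score - 20))`).
#' @param biomarker_drift per-day upward drift of the latent
#'   log-biomarkers for progressors.
#' @param progressor_fraction fraction of patients whose disease
#'   progresses.
#' @param init_meanlog,init_sdlog log-scale location/spread of the initial
#'   biomarker distribution (creatinine, bilirubin, INR).
#' @param dialysis_init_logit intercept of the logit probability of
#'   already being on biweekly dialysis at listing,
#'   `plogis(intercept + slope * log creatinine)` — most dialysis in a
#'   cirrhosis waitlist cohort is prevalent at registration.
#' @param dialysis_base,dialysis_slope daily hazard of *starting*
#'   biweekly dialysis while listed: `base * exp(slope * log latent
#'   creatinine)`; dialysis is absorbing.
#' @param recert_schedule data.frame `(min_score, max_age_days)`: maximum
#'   report age by rounded UNOS-MELD band; default 365 d below 10, 90 d for
#'   10-18, 30 d for 19-24, 7 d for 25 and above.
#' @param voluntary_report_prob daily probability of an unforced report.
#' @param nt_fraction fraction of patients given one NT interval.
#' @param nt_mean_duration mean NT duration in days.
#' @param seed integer seed; the simulation is a pure function of the
#'   config.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(
    n_patients = 1000L,
    window_start = as.Date("2014-01-01"),
    window_end = as.Date("2015-12-31"),
    countries = data.frame(code = c("DE", "NL"),
                           centers = c(5L, 2L),
                           share = c(0.7, 0.3)),
    true_beta = c(crea = 2.15, bili = 0.97, inr = 2.22, dialysis = 1.86),
    baseline_death_hazard = 1.4e-4,
    transplant_model = c("independent", "score_dependent"),
    transplant_base = 0.004,
    gamma_tx = 0,
    delisting_model = c("independent", "score_dependent"),
    delisting_base = 0.0015,
    gamma_dl = 0,
    biomarker_volatility = c(crea = 0.010, bili = 0.012, inr = 0.008),
    volatility_severity = 0.03,
    biomarker_drift = c(crea = 0.0010, bili = 0.0020, inr = 0.0010),
    progressor_fraction = 0.3,
    init_meanlog = c(crea = 0.05, bili = 0.80, inr = 0.30),
    init_sdlog = c(crea = 0.40, bili = 1.00, inr = 0.35),
    dialysis_init_logit = -2.5,
    dialysis_base = 3e-4,
    dialysis_slope = 2.0,
    recert_schedule = data.frame(min_score = c(6L, 10L, 19L, 25L),
                                 max_age_days = c(365L, 90L, 30L, 7L)),
    voluntary_report_prob = 0.005,
    nt_fraction = 0.05,
    nt_mean_duration = 30,
    seed = 1L) {
  transplant_model <- match.arg(transplant_model)
  delisting_model <- match.arg(delisting_model)
  window_start <- as.Date(window_start); window_end <- as.Date(window_end)
  if (is.na(window_end) || !is.finite(as.integer(window_end)))
    stop("no termination: a finite window_end (data cutoff) is required")
  if (window_end <= window_start) stop("window_end must follow window_start")
  hz <- c(baseline_death_hazard, transplant_base, delisting_base,
          dialysis_base)
  if (any(hz < 0)) stop("hazards must be non-negative")
  if (progressor_fraction < 0 || progressor_fraction > 1)
    stop("progressor_fraction must be in [0, 1]")
  if (abs(sum(countries$share) - 1) > 1e-8)
    stop("country shares must sum to 1")
  cfg <- list(n_patients = as.integer(n_patients),
              window_start = window_start, window_end = window_end,
              countries = countries, true_beta = true_beta,
              baseline_death_hazard = baseline_death_hazard,
              transplant_model = transplant_model,
              transplant_base = transplant_base, gamma_tx = gamma_tx,
              delisting_model = delisting_model,
              delisting_base = delisting_base, gamma_dl = gamma_dl,
              biomarker_volatility = biomarker_volatility,
              volatility_severity = volatility_severity,
              biomarker_drift = biomarker_drift,
              progressor_fraction = progressor_fraction,
              init_meanlog = init_meanlog, init_sdlog = init_sdlog,
              dialysis_init_logit = dialysis_init_logit,
              dialysis_base = dialysis_base,
              dialysis_slope = dialysis_slope,
              recert_schedule = recert_schedule,
              voluntary_report_prob = voluntary_report_prob,
              nt_fraction = nt_fraction,
              nt_mean_duration = nt_mean_duration,
              seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  cfg
}

#' Named default scenarios
#'
#' Two scenarios sharing the same true death coefficients:
#' \describe{
#'   \item{`A_independent`}{transplant and delisting hazards constant
#'     (`gamma = 0`), so censoring is independent and the naive
#'     (unweighted) from-cross-section Cox fit is consistent;}
#'   \item{`B_informative`}{transplant and delisting hazards log-linear in
#'     the currently reported UNOS-MELD score (`gamma_tx > 0`,
#'     `gamma_dl > 0`), calibrated so the 90-day transplant fraction rises
#'     steeply across UNOS-MELD bands; censoring is then informative and
#'     the naive fit is biased while IPCW corrects it.}
#' }
#'
#' @param n_patients patients per simulated registry.
#' @param seed simulation seed.
#' @return named list of [simulation_config()] objects.
#' @export
default_scenarios <- function(n_patients = 3000L, seed = 1L) {
  list(
    A_independent = simulation_config(
      n_patients = n_patients,
      transplant_model = "independent", transplant_base = 0.004,
      gamma_tx = 0,
      delisting_model = "independent", delisting_base = 0.0015,
      gamma_dl = 0,
      seed = seed),
    B_informative = simulation_config(
      n_patients = n_patients,
      transplant_model = "score_dependent", transplant_base = 0.0035,
      gamma_tx = 0.15,
      delisting_model = "score_dependent", delisting_base = 5e-4,
      gamma_dl = 0.04,
      seed = seed))
}

# continuous UNOS-MELD of reported values, used by the recertification
# schedule and the score-dependent censoring hazards
unos_of <- function(crea, bili, inr, dial) {
  cr <- crea
  cr[dial] <- 4.0
  cr <- pmin(pmax(cr, 1.0), 4.0)
  bi <- pmax(bili, 1.0)
  ir <- pmax(inr, 1.0)
  6.43 + 9.57 * log(cr) + 3.78 * log(bi) + 11.20 * log(ir)
}

#' Simulate a waitlist registry with known ground truth
#'
#' See the package vignette for the generative model.  The simulation is
#' day-granular and fully reproducible from `config$seed` (the caller's
#' RNG state is left untouched).
#'
#' @param config a [simulation_config()].
#' @return list with elements `registry` (a [registry()] with cutoff
#'   `window_end`) and `ground_truth` (true coefficients, per-patient
#'   progressor flags, exit day and cause).
#' @export
simulate_registry <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(config$seed)

  n <- config$n_patients
  D <- as.integer(config$window_end - config$window_start)
  pid <- sprintf("P%06d", seq_len(n))

  # geography
  ctry_idx <- sample.int(nrow(config$countries), n, replace = TRUE,
                         prob = config$countries$share)
  country <- config$countries$code[ctry_idx]
  center <- character(n)
  for (k in seq_len(nrow(config$countries))) {
    sel <- ctry_idx == k
    nc <- config$countries$centers[k]
    center[sel] <- paste0(config$countries$code[k], "C",
                          sample.int(nc, sum(sel), replace = TRUE,
                                     prob = seq_len(nc)))
  }

  reg_day <- sample.int(D, n, replace = TRUE) - 1L
  progressor <- stats::runif(n) < config$progressor_fraction

  vol <- config$biomarker_volatility
  drf <- config$biomarker_drift
  beta <- config$true_beta
  sched <- config$recert_schedule[order(config$recert_schedule$min_score), ]

  # latent state (log scale), reported state, bookkeeping
  lcrea <- lbili <- linr <- rep.int(NA_real_, n)
  dial <- rep.int(FALSE, n)
  r_crea <- r_bili <- r_inr <- rep.int(NA_real_, n)
  r_dial <- rep.int(FALSE, n)
  r_score <- rep.int(NA_real_, n)
  last_rep <- rep.int(NA_integer_, n)
  exited <- rep.int(FALSE, n)
  exit_day <- rep.int(NA_integer_, n)
  exit_cause <- rep.int(NA_character_, n)

  rep_day_l <- vector("list", D)
  rep_pid_l <- vector("list", D)
  rep_val_l <- vector("list", D)

  tx_hazard <- function(score) {
    if (config$transplant_model == "independent")
      rep.int(config$transplant_base, length(score))
    else config$transplant_base * exp(config$gamma_tx * (score - 20))
  }
  dl_hazard <- function(score) {
    if (config$delisting_model == "independent")
      rep.int(config$delisting_base, length(score))
    else config$delisting_base * exp(config$gamma_dl * (score - 20))
  }

  for (d in 0:(D - 1L)) {
    newly <- which(reg_day == d)
    if (length(newly)) {
      m <- length(newly)
      lcrea[newly] <- stats::rnorm(m, config$init_meanlog["crea"],
                                   config$init_sdlog["crea"])
      lbili[newly] <- stats::rnorm(m, config$init_meanlog["bili"],
                                   config$init_sdlog["bili"])
      linr[newly] <- stats::rnorm(m, config$init_meanlog["inr"],
                                  config$init_sdlog["inr"])
      dial[newly] <- stats::runif(m) <
        stats::plogis(config$dialysis_init_logit +
                        config$dialysis_slope * lcrea[newly])
    }
    act <- which(reg_day <= d & !exited)
    if (!length(act)) next
    m <- length(act)
    old <- act[reg_day[act] < d]
    if (length(old)) {
      mo <- length(old)
      step_drift <- ifelse(progressor[old], 1, 0)
      # severity-dependent lability: sicker patients' biomarkers move
      # more from day to day
      sev <- unos_of(exp(lcrea[old]), exp(lbili[old]), exp(linr[old]),
                     dial[old])
      vmult <- pmin(exp(config$volatility_severity * (sev - 20)), 4)
      lcrea[old] <- lcrea[old] + step_drift * drf["crea"] +
        stats::rnorm(mo, 0, vol["crea"] * vmult)
      lbili[old] <- lbili[old] + step_drift * drf["bili"] +
        stats::rnorm(mo, 0, vol["bili"] * vmult)
      linr[old] <- linr[old] + step_drift * drf["inr"] +
        stats::rnorm(mo, 0, vol["inr"] * vmult)
      # dialysis onset (absorbing), driven by latent creatinine
      nd <- old[!dial[old]]
      if (length(nd)) {
        h_dial <- config$dialysis_base *
          exp(config$dialysis_slope * lcrea[nd])
        dial[nd] <- stats::runif(length(nd)) < (1 - exp(-h_dial))
      }
    }
    # reporting: mandatory at registration, on recertification expiry,
    # and voluntarily
    age <- d - last_rep[act]
    need_new <- is.na(last_rep[act])
    limit <- rep.int(Inf, m)
    has_score <- !need_new
    if (any(has_score)) {
      band <- findInterval(round(r_score[act][has_score]),
                           sched$min_score)
      band[band < 1L] <- 1L
      limit[has_score] <- sched$max_age_days[band]
    }
    vol_rep <- stats::runif(m) < config$voluntary_report_prob
    do_rep <- need_new | (age >= limit) | vol_rep
    rep_idx <- act[do_rep]
    if (length(rep_idx)) {
      r_crea[rep_idx] <- exp(lcrea[rep_idx])
      r_bili[rep_idx] <- exp(lbili[rep_idx])
      r_inr[rep_idx] <- exp(linr[rep_idx])
      r_dial[rep_idx] <- dial[rep_idx]
      r_score[rep_idx] <- unos_of(r_crea[rep_idx], r_bili[rep_idx],
                                  r_inr[rep_idx], r_dial[rep_idx])
      last_rep[rep_idx] <- d
      rep_day_l[[d + 1L]] <- rep(d, length(rep_idx))
      rep_pid_l[[d + 1L]] <- rep_idx
      rep_val_l[[d + 1L]] <- cbind(r_crea[rep_idx], r_bili[rep_idx],
                                   r_inr[rep_idx],
                                   as.integer(r_dial[rep_idx]))
    }
    # hazards for the day (d, d+1], driven by *reported* values
    crea_adj <- ifelse(r_dial[act], 1.0, r_crea[act])
    lp_death <- beta["crea"] * log(crea_adj) +
      beta["bili"] * log(r_bili[act]) +
      beta["inr"] * log(r_inr[act]) +
      beta["dialysis"] * r_dial[act]
    h_death <- config$baseline_death_hazard * exp(lp_death)
    h_tx <- tx_hazard(r_score[act])
    h_dl <- dl_hazard(r_score[act])
    h_tot <- h_death + h_tx + h_dl
    u <- stats::runif(m)
    hit <- u < (1 - exp(-h_tot))
    if (any(hit)) {
      who <- act[hit]
      # cause | event: probabilities proportional to cause hazards
      pc <- cbind(h_death[hit], h_tx[hit], h_dl[hit]) / h_tot[hit]
      v <- stats::runif(length(who))
      cause <- ifelse(v < pc[, 1L], "death",
                      ifelse(v < pc[, 1L] + pc[, 2L], "transplant",
                             "delisting"))
      exited[who] <- TRUE
      exit_day[who] <- d + 1L
      exit_cause[who] <- cause
    }
  }

  # post-delisting death: the death process continues for 90 days with
  # hazards frozen at the delisting-time reported values
  delisted <- which(exit_cause == "delisting")
  pd_death_day <- rep.int(NA_integer_, n)
  pd_followup <- rep.int(NA_integer_, n)
  if (length(delisted)) {
    crea_adj <- ifelse(r_dial[delisted], 1.0, r_crea[delisted])
    h_frozen <- config$baseline_death_hazard *
      exp(beta["crea"] * log(crea_adj) +
            beta["bili"] * log(r_bili[delisted]) +
            beta["inr"] * log(r_inr[delisted]) +
            beta["dialysis"] * r_dial[delisted])
    tdead <- stats::rexp(length(delisted), rate = pmax(h_frozen, 1e-12))
    died <- tdead <= 90
    pd_death_day[delisted[died]] <- exit_day[delisted[died]] +
      as.integer(ceiling(tdead[died]))
    pd_followup[delisted] <- pmin(as.integer(ceiling(tdead)), 90L)
  }

  # NT intervals for a random subset (does not alter hazards; only
  # cross-section eligibility)
  nt <- NULL
  stay_end <- ifelse(exited, exit_day, D)
  eligible <- which((stay_end - reg_day) > 10L)
  n_nt <- round(config$nt_fraction * n)
  if (n_nt > 0L && length(eligible)) {
    pick <- eligible[sample.int(length(eligible),
                                min(n_nt, length(eligible)))]
    off <- floor(stats::runif(length(pick)) *
                   (stay_end[pick] - reg_day[pick] - 1L)) + 1L
    nt_start <- reg_day[pick] + off
    nt_len <- 1L + stats::rgeom(length(pick),
                                1 / config$nt_mean_duration)
    nt <- data.frame(
      patient_id = pid[pick],
      start_date = config$window_start + nt_start,
      end_date = pmin(config$window_start + nt_start + nt_len,
                      config$window_end),
      status = "NT")
  }

  reports <- data.frame(
    patient_id = pid[unlist(rep_pid_l)],
    report_date = config$window_start + unlist(rep_day_l),
    do.call(rbind, rep_val_l))
  names(reports)[3:6] <- c("creatinine", "bilirubin", "inr", "dialysis")

  registrations <- data.frame(
    patient_id = pid, center_id = center, country = country,
    registration_date = config$window_start + reg_day,
    exit_date = config$window_start +
      ifelse(exited, exit_day, NA_integer_),
    exit_reason = ifelse(exited, exit_cause, "censored"),
    post_delisting_death_date = config$window_start + pd_death_day,
    post_delisting_followup_days = pd_followup)

  reg <- registry(registrations, reports, nt,
                  cutoff = config$window_end)
  gt <- list(true_beta = beta,
             transplant = list(model = config$transplant_model,
                               base = config$transplant_base,
                               gamma = config$gamma_tx),
             delisting = list(model = config$delisting_model,
                              base = config$delisting_base,
                              gamma = config$gamma_dl),
             progressor = stats::setNames(progressor, pid),
             exit_day = stats::setNames(exit_day, pid),
             exit_cause = stats::setNames(exit_cause, pid))
  list(registry = reg, ground_truth = gt)
}
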