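# exponential-censoring fixture: constant transplant and delisting
# hazards with known rates, no deaths, one report per patient
exp_censoring_registry <- function(n = 4000, rate_T = 0.01,
                                   rate_D = 0.005, seed = 21) {
  set.seed(seed)
  t_T <- rexp(n, rate_T)
  t_D <- rexp(n, rate_D)
  t <- pmin(ceiling(pmin(t_T, t_D)), 200)
  reason <- ifelse(pmin(t_T, t_D) > 200, "censored",
                   ifelse(t_T < t_D, "transplant", "delisting"))
  start <- as.Date("2014-01-01")
  regs <- data.frame(
    patient_id = sprintf("e%05d", seq_len(n)), center_id = "C1",
    country = "XX", registration_date = start,
    exit_date = start + ifelse(reason == "censored", NA_integer_, t),
    exit_reason = reason,
    post_delisting_death_date = as.Date(NA),
    post_delisting_followup_days = NA_integer_)
  reps <- data.frame(patient_id = regs$patient_id, report_date = start,
                     creatinine = 1.2, bilirubin = 2, inr = 1.2,
                     dialysis = 0L)
  registry(regs, reps, NULL, cutoff = start + 400)
}

test_that("unstabilized weights reproduce the exponential closed form", {
  x <- exp_censoring_registry()
  cs <- build_cross_section_dataset(x, as.Date("2014-01-01"),
                                    horizon_days = 90)
  mT <- fit_censoring_model(cs, x, "transplant", covariates = "none")
  mD <- fit_censoring_model(cs, x, "delisting", covariates = "none")
  w <- compute_weights(cs, mT, mD, x, stabilize = FALSE,
                       truncation_quantile = NULL)
  # at t = 30 the joint weight is exp((0.01 + 0.005) * 30) ~ 1.568
  sel <- w$tstop == 30
  expect_gt(sum(sel), 10)
  expect_equal(mean(w$weight[sel]), exp(0.015 * 30), tolerance = 0.05)
  # weights never below 1 before stabilization, and 1 at t = 0
  expect_true(all(w$weight >= 1))
  short <- w$weight[w$tstop <= 2]
  expect_true(all(abs(short - 1) < 0.15))
})

test_that("weights grow along follow-up and stabilized weights center at 1", {
  sim <- small_sim("B_informative", n = 600, seed = 9)
  cs <- build_cross_section_dataset(sim$registry, weekly_grid())
  mT <- fit_censoring_model(cs, sim$registry, "transplant")
  mD <- fit_censoring_model(cs, sim$registry, "delisting")
  raw <- compute_weights(cs, mT, mD, sim$registry, stabilize = FALSE,
                         truncation_quantile = NULL)
  mono <- tapply(seq_len(nrow(raw)), raw$row_id, function(i) {
    all(diff(raw$weight[i][order(raw$tstop[i])]) >= -1e-12)
  })
  expect_true(all(mono))
  expect_true(all(raw$weight >= 1 - 1e-12))
  stab <- compute_weights(cs, mT, mD, sim$registry, stabilize = TRUE)
  expect_equal(mean(stab$weight[stab$last]), 1, tolerance = 0.05)
})

test_that("null censoring models with stabilization give unit weights and leave the fit unchanged", {
  sim <- small_sim("A_independent", n = 400, seed = 5)
  cs <- build_cross_section_dataset(sim$registry, weekly_grid())
  mT <- fit_censoring_model(cs, sim$registry, "transplant",
                            covariates = "none")
  mD <- fit_censoring_model(cs, sim$registry, "delisting",
                            covariates = "none")
  w <- compute_weights(cs, mT, mD, sim$registry, stabilize = TRUE,
                       truncation_quantile = NULL)
  expect_lt(max(abs(w$weight - 1)), 1e-10)
  unweighted <- fit_mortality_model(cs)
  weighted <- fit_mortality_model(w)
  expect_equal(weighted$coefficients, unweighted$coefficients,
               tolerance = 1e-6)
  expect_equal(weighted$loglik[2], unweighted$loglik[2],
               tolerance = 1e-8)
})

test_that("the censoring fit equals brute-force partial likelihood maximization", {
  sim <- small_sim("B_informative", n = 30, seed = 13)
  cs <- build_cross_section_dataset(sim$registry, weekly_grid())
  fit <- fit_censoring_model(cs, sim$registry, "transplant")
  long <- dynmeld:::censoring_counting_data(cs, sim$registry)
  ev <- as.integer(long$last & !is.na(long$censor_cause) &
                     long$censor_cause == "transplant")
  X <- as.matrix(dynmeld:::alloc_covariates(long))
  # day-granular ties exist; refit with Breslow ties to match the
  # Breslow oracle exactly
  dd <- data.frame(tstart = long$tstart, tstop = long$tstop, ev = ev,
                   X, stratum = long$country)
  ref <- survival::coxph(
    survival::Surv(tstart, tstop, ev) ~ lcrea + lbili + linr +
      dialysis + survival::strata(stratum),
    data = dd, ties = "breslow")
  opt <- optim(rep(0, 4), ncox_loglik, tstart = long$tstart,
               tstop = long$tstop, ev = ev, X = X,
               w = rep(1, nrow(long)), strata = long$country,
               method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  expect_equal(unname(coef(ref)), opt$par, tolerance = 1e-6)
  # Efron vs Breslow differences stay within a fraction of an SE here
  expect_equal(unname(fit$coefficients), opt$par, tolerance = 0.2)
})

test_that("informative transplant selection is visible in the censoring model", {
  sim <- small_sim("B_informative", n = 1500, seed = 17)
  cs <- build_cross_section_dataset(sim$registry, weekly_grid())
  mT <- fit_censoring_model(cs, sim$registry, "transplant")
  # gamma_tx > 0 on the score implies positive coefficients on all
  # three allocation-scale log biomarkers
  expect_true(all(mT$coefficients[c("lcrea", "lbili", "linr")] > 0))
  # with a truly constant transplant hazard (and negligible competing
  # mortality, so day-granular competition cannot leak in) the fitted
  # covariate coefficients are null
  cfg <- simulation_config(n_patients = 1500,
                           baseline_death_hazard = 1e-6,
                           transplant_model = "independent",
                           transplant_base = 0.004,
                           delisting_model = "independent",
                           delisting_base = 0.0015, seed = 17)
  simN <- simulate_registry(cfg)
  csN <- build_cross_section_dataset(simN$registry, weekly_grid())
  mTN <- fit_censoring_model(csN, simN$registry, "transplant")
  expect_true(all(abs(mTN$coefficients) <= 2.5 * mTN$robust_se))
  mDN <- fit_censoring_model(csN, simN$registry, "delisting")
  expect_true(all(abs(mDN$coefficients) <= 2.5 * mDN$robust_se))
})

test_that("rows without events of a cause are rejected", {
  x <- exp_censoring_registry(n = 50, rate_T = 0.01, rate_D = 1e-9)
  cs <- build_cross_section_dataset(x, as.Date("2014-01-01"))
  expect_error(fit_censoring_model(cs, x, "delisting"),
               "cannot estimate weights")
})
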