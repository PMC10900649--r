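test_that("the mortality fit equals brute-force partial likelihood maximization", {
  d <- cox_fixture()   # distinct event times: Efron == Breslow
  fit <- fit_mortality_model(d)
  X <- as.matrix(dynmeld:::mortality_covariates(d))
  opt <- optim(rep(0, 4), ncox_loglik, tstart = rep(0, nrow(d)),
               tstop = d$time_days, ev = as.integer(d$event), X = X,
               w = rep(1, nrow(d)), strata = d$stratum,
               method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-15))
  expect_equal(unname(fit$coefficients), opt$par, tolerance = 1e-6)
  expect_equal(fit$loglik[2], -opt$value, tolerance = 1e-8)

  # and the weighted fit against the weighted oracle
  set.seed(31)
  w <- data.frame(d, row_id = seq_len(nrow(d)), tstart = 0,
                  tstop = d$time_days, ev = as.integer(d$event),
                  weight = exp(runif(nrow(d), 0, 0.5)))
  class(w) <- c("ipcw_rows", "data.frame")
  wfit <- fit_mortality_model(w)
  wopt <- optim(rep(0, 4), ncox_loglik, tstart = w$tstart,
                tstop = w$tstop, ev = w$ev, X = X, w = w$weight,
                strata = w$stratum, method = "BFGS",
                control = list(maxit = 1000, reltol = 1e-15))
  expect_equal(unname(wfit$coefficients), wopt$par, tolerance = 1e-6)
  # unit weights reproduce the unweighted fit
  w$weight <- 1
  expect_equal(fit_mortality_model(w)$coefficients, fit$coefficients,
               tolerance = 1e-8)
})

test_that("likelihood-ratio arithmetic matches the printed pairs", {
  expect_equal(lr_test(0, df = 3)$p_value, 1)
  expect_equal(round(lr_test(4.1, df = 3)$p_value, 2), 0.25)
  expect_lt(lr_test(801, df = 3)$p_value, 0.001)
  expect_equal(lr_test(-100.0, -102.05, df = 3)$statistic, 4.1)
  expect_error(lr_test(-1, df = 3), "not nested")
})

test_that("the offset enters on the log-hazard scale with a 3-df test", {
  sim <- small_sim("A_independent", n = 400, seed = 5)
  cs <- build_cross_section_dataset(sim$registry, weekly_grid())
  defs <- meld_definitions()
  f <- fit_mortality_model(cs, caps = defs$remeld$bounds,
                           dialysis_as_covariate = FALSE,
                           offset_score = defs$remeld,
                           offset_scale = 4.0)
  expect_equal(f$df, 3L)
  expect_equal(f$offset$scale, 4.0)
  expect_gte(lr_test(f)$statistic, 0)
  # offset scale is estimated when not supplied
  f2 <- fit_mortality_model(cs, caps = defs$remeld$bounds,
                            dialysis_as_covariate = FALSE,
                            offset_score = defs$remeld)
  expect_gt(f2$offset$scale, 0)
})

test_that("the cap search is an argmax and degenerate grids pass through", {
  sim <- small_sim("A_independent", n = 400, seed = 5)
  cs <- build_cross_section_dataset(sim$registry, weekly_grid())
  one <- list(creatinine = list(lower = 0.8, upper = 2.5),
              bilirubin = list(lower = 0.6, upper = 55),
              inr = list(lower = 1.0, upper = 3.0))
  res <- optimize_caps(cs, search_grid = one)
  expect_equal(res$caps$creatinine, c(0.8, 2.5))
  grid <- list(creatinine = list(lower = c(0.6, 1.0),
                                 upper = c(2.5, 4.0)),
               bilirubin = list(lower = 0.6, upper = c(27, 55)),
               inr = list(lower = 1.0, upper = c(2.6, 3.0)))
  res <- optimize_caps(cs, search_grid = grid)
  expect_true(all(res$profile$loglik <= res$loglik + 1e-9))
  ll_at <- function(caps) fit_mortality_model(cs, caps)$loglik[2]
  expect_equal(res$loglik, ll_at(res$caps))
})

test_that("a simulated log-hazard plateau is recovered by the cap search", {
  # creatinine effect saturates above 2.5: the search should prefer an
  # upper cap near 2.5 over 6.0
  set.seed(41)
  n <- 4000
  d <- data.frame(
    patient_id = sprintf("s%05d", 1:n), country = "XX", stratum = "XX",
    creatinine = exp(rnorm(n, 0.4, 0.6)),
    bilirubin = exp(rnorm(n, 0.7, 0.8)),
    inr = exp(rnorm(n, 0.3, 0.3)), dialysis = 0L)
  lp <- 2.0 * log(pmin(d$creatinine, 2.5)) + 0.8 * log(d$bilirubin) +
    1.5 * log(d$inr)
  tdeath <- rexp(n, 0.002 * exp(lp))
  d$time_days <- pmin(tdeath, 90)
  d$event <- tdeath <= 90
  d$censor_cause <- ifelse(d$event, NA, "horizon")
  class(d) <- c("cs_rows", "data.frame")
  grid <- list(creatinine = list(lower = 0.1, upper = c(2.0, 2.5, 3.0, 6.0)),
               bilirubin = list(lower = 0.1, upper = 100),
               inr = list(lower = 0.1, upper = 100))
  res <- optimize_caps(d, search_grid = grid,
                       dialysis_as_covariate = FALSE)
  expect_lte(res$caps$creatinine[2], 3.0)  # within one grid step of 2.5
})

test_that("quantile matching recovers affine maps and scales inversely", {
  set.seed(43)
  lp <- rnorm(500)
  ref <- 4.24 * lp + 6.43
  qm <- quantile_match(lp, ref)
  expect_equal(qm$a, 4.24, tolerance = 1e-10)
  expect_equal(qm$b, 6.43, tolerance = 1e-10)
  qm2 <- quantile_match(2 * lp, ref)
  expect_equal(qm2$a, 4.24 / 2, tolerance = 1e-10)
  expect_error(quantile_match(rep(1, 10), 1:10), "zero variance")
})

test_that("rescaling the printed cross-section IPCW coefficients reproduces DynReMELD", {
  # ratio consistency: the published DynReMELD coefficients over the
  # published Cox coefficients share a single scale
  ratios <- c(9.12 / 2.15, 4.14 / 0.97, 9.42 / 2.22)
  expect_true(all(ratios > 4.23 & ratios < 4.28))
  fit <- structure(list(
    coefficients = c(lcrea = 2.15, lbili = 0.97, linr = 2.22,
                     dialysis = 1.86),
    caps = meld_definitions()$dynremeld$bounds,
    dialysis_as_covariate = TRUE), class = "meld_coxfit")
  sc <- derive_score(fit, scale = 9.12 / 2.15, shift = 8.50,
                     name = "check")
  expect_equal(sc$intercept, 8.50)
  expect_equal(sc$coef_crea, 9.12)
  expect_equal(sc$coef_bili, 4.14, tolerance = 0.04)
  expect_equal(sc$coef_inr, 9.42, tolerance = 0.04)
  expect_equal(sc$dialysis_crea, 2.5)
  # dialysis-equivalent creatinine close to the 2.5 upper cap
  expect_equal(dialysis_equivalent_creatinine(fit), 2.4,
               tolerance = 0.05)
  expect_equal(dialysis_equivalent_creatinine(1.86, 2.15),
               exp(1.86 / 2.15))
})

test_that("an identity rescale returns the Cox coefficients and preserves ranking", {
  d <- cox_fixture()
  fit <- fit_mortality_model(d, caps = meld_definitions()$dynremeld$bounds)
  sc <- derive_score(fit, scale = 1, shift = 0, name = "identity")
  expect_equal(sc$coef_crea, round(fit$coefficients[["lcrea"]], 2))
  big <- derive_score(fit, scale = 10, shift = 5, name = "scaled")
  # a > 0 affine map: identical ordering up to coefficient rounding —
  # on non-dialysis reports (the deployed score replaces the fitted
  # dialysis term by the creatinine-substitution rule)
  nd <- d[d$dialysis == 0L, ]
  s1 <- meld_score(big, nd$creatinine, nd$bilirubin, nd$inr, FALSE)
  lp <- predict_lp(fit, nd)
  expect_gt(cor(rank(s1), rank(lp)), 0.999)
})
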