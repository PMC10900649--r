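# End-to-end orchestration: simulate/read -> validate -> split -> build
# datasets -> censoring models & weights -> Table-2-style fits -> derive
# score -> validate against reference scores.

#' Pipeline configuration
#'
#' @param scenario a [simulation_config()] to simulate from, or `NULL`
#'   when reading CSVs.
#' @param paths named list `(registrations, reports, statuses)` of CSV
#'   paths when not simulating.
#' @param cutoff data cutoff when reading CSVs.
#' @param spacing_days cross-section spacing (default weekly).
#' @param horizon_days outcome horizon.
#' @param dev_fraction development share of the center split.
#' @param single_center_countries countries split at random.
#' @param caps `"default"` (DynReMELD-style 0.8-2.5 / 0.6-55 / 1.0-3.0),
#'   `"optimize"` (profile-likelihood search), or a named list of bounds.
#' @param ipcw list of IPCW switches: `stabilize`,
#'   `truncation_quantile`, `time_varying`, `covariates`.
#' @param quantile_probs percentile grid for quantile matching.
#' @param n_boot bootstrap replicates in evaluation (0 = none).
#' @param score_range integer scores for the risk table.
#' @param seeds named integer seeds, one per stochastic stage
#'   (`split`, `boot`).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(scenario = NULL, paths = NULL,
                            cutoff = as.Date("2019-12-31"),
                            spacing_days = 7L, horizon_days = 90L,
                            dev_fraction = 0.7,
                            single_center_countries = character(),
                            caps = "default",
                            ipcw = list(stabilize = TRUE,
                                        truncation_quantile = 0.99,
                                        time_varying = TRUE,
                                        covariates = "allocation"),
                            quantile_probs = (1:99) / 100,
                            n_boot = 0L, score_range = 20:40,
                            seeds = list(split = 11L, boot = 12L)) {
  if (is.null(scenario) && is.null(paths))
    stop("either a simulation scenario or CSV paths must be given")
  structure(list(scenario = scenario, paths = paths, cutoff = cutoff,
                 spacing_days = spacing_days,
                 horizon_days = horizon_days,
                 dev_fraction = dev_fraction,
                 single_center_countries = single_center_countries,
                 caps = caps, ipcw = ipcw,
                 quantile_probs = quantile_probs, n_boot = n_boot,
                 score_range = score_range, seeds = seeds),
            class = "pipeline_config")
}

#' Run the full score-revision pipeline
#'
#' Simulates (or reads) a registry, validates it, splits it into
#' development and validation cohorts by center, builds the
#' from-registration and from-cross-section datasets, fits the censoring
#' models and IPCW weights on the development cohort, produces the three
#' Table-2-style fits per design (reference-score offset / refit without
#' IPCW / refit with IPCW), derives a quantile-matched score from the
#' IPCW cross-section fit, and evaluates the derived score against
#' UNOS-MELD and ReMELD in the validation cohort (truncated c-indices and
#' a per-score risk table with and without IPCW).
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory for stage artifacts (registry CSVs
#'   and a JSON run report).
#' @return list of class `meld_run_report`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  defs <- meld_definitions()

  # stage 1: data
  if (!is.null(config$scenario)) {
    sim <- simulate_registry(config$scenario)
    reg0 <- sim$registry
    ground_truth <- sim$ground_truth
  } else {
    reg0 <- read_registry(config$paths$registrations,
                          config$paths$reports, config$paths$statuses,
                          cutoff = config$cutoff)
    ground_truth <- NULL
  }

  # stage 2: validation / exclusions
  val <- validate_registry(reg0)
  reg <- val$registry

  # stage 3: center split
  split <- center_split(reg, dev_fraction = config$dev_fraction,
                        single_center_countries =
                          config$single_center_countries,
                        seed = config$seeds$split)
  dev <- split$development
  hold <- split$validation

  # stage 4: analysis datasets
  grid <- cross_section_dates(min(dev$registrations$registration_date),
                              reg$cutoff - 1L,
                              spacing_days = config$spacing_days)
  cs_dev <- build_cross_section_dataset(dev, grid,
                                        config$horizon_days)
  fr_dev <- build_from_registration_dataset(dev, config$horizon_days)
  cs_hold <- build_cross_section_dataset(hold, grid,
                                         config$horizon_days)
  fr_hold <- build_from_registration_dataset(hold, config$horizon_days)

  # stage 5: censoring models and weights (development only)
  mT <- fit_censoring_model(cs_dev, dev, "transplant",
                            covariates = config$ipcw$covariates,
                            time_varying = config$ipcw$time_varying)
  mD <- fit_censoring_model(cs_dev, dev, "delisting",
                            covariates = config$ipcw$covariates,
                            time_varying = config$ipcw$time_varying)
  w_dev <- compute_weights(cs_dev, mT, mD, dev,
                           stabilize = config$ipcw$stabilize,
                           truncation_quantile =
                             config$ipcw$truncation_quantile)

  # stage 6: caps
  caps <- if (identical(config$caps, "default")) {
    defs$dynremeld$bounds
  } else if (identical(config$caps, "optimize")) {
    optimize_caps(cs_dev)$caps
  } else config$caps

  # stage 7: Table-2-style fits, from cross-section
  fits <- list(
    cs_offset = fit_mortality_model(cs_dev, caps = caps,
                                    dialysis_as_covariate = FALSE,
                                    offset_score = defs$remeld),
    cs_refit = fit_mortality_model(cs_dev, caps = caps),
    cs_ipcw = fit_mortality_model(w_dev, caps = caps),
    fr_refit = fit_mortality_model(fr_dev, caps = caps))

  # stage 8: quantile-matched score from the IPCW cross-section fit
  lp <- predict_lp(fits$cs_ipcw, cs_dev)
  unos_pts <- meld_score(defs$unos, cs_dev$creatinine,
                         cs_dev$bilirubin, cs_dev$inr,
                         cs_dev$dialysis == 1L)
  qm <- quantile_match(lp, unos_pts, probs = config$quantile_probs)
  derived <- derive_score(fits$cs_ipcw, qm$a, qm$b, caps = caps,
                          name = "revised (cross-section, IPCW)")

  # stage 9: validation-cohort evaluation
  scores <- list(unos = defs$unos, remeld = defs$remeld,
                 derived = derived)
  cindex <- lapply(scores, function(def)
    truncated_cindex(cs_hold, def, config$horizon_days,
                     n_boot = config$n_boot,
                     seed = config$seeds$boot))
  dedup <- dedup_first_cross_section(cs_dev)
  w_dedup <- compute_weights(dedup, mT, mD, dev,
                             stabilize = config$ipcw$stabilize,
                             truncation_quantile =
                               config$ipcw$truncation_quantile)
  risks <- list(
    unweighted = absolute_risk_table(dedup, derived,
                                     config$score_range,
                                     config$horizon_days,
                                     n_boot = config$n_boot,
                                     seed = config$seeds$boot),
    ipcw = absolute_risk_table(w_dedup, derived, config$score_range,
                               config$horizon_days,
                               n_boot = config$n_boot,
                               seed = config$seeds$boot))

  report <- list(
    config = config,
    exclusions = val$exclusions,
    n_dev = length(unique(dev$registrations$patient_id)),
    n_val = length(unique(hold$registrations$patient_id)),
    n_cs_rows = nrow(cs_dev), n_fr_rows = nrow(fr_dev),
    weight_summary = summary(w_dev$weight),
    fits = fits, quantile_match = qm, derived_score = derived,
    cindex = cindex, risks = risks,
    ground_truth = ground_truth)
  class(report) <- "meld_run_report"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_registry(reg, file.path(out_dir, "registry"))
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      jsonlite::write_json(
        report_json(report), file.path(out_dir, "run_report.json"),
        auto_unbox = TRUE, digits = 10, pretty = TRUE)
    }
  }
  report
}

# JSON-serializable view of a run report
report_json <- function(report) {
  fit_view <- function(f)
    list(coefficients = as.list(f$coefficients),
         robust_se = as.list(f$robust_se),
         lr_statistic = f$lr_statistic, df = f$df,
         n = f$n, events = f$n_events)
  list(
    exclusions = report$exclusions,
    n_dev = report$n_dev, n_val = report$n_val,
    n_cs_rows = report$n_cs_rows, n_fr_rows = report$n_fr_rows,
    fits = lapply(report$fits, fit_view),
    quantile_match = report$quantile_match,
    derived_score = unclass(report$derived_score),
    cindex = lapply(report$cindex, function(ci)
      list(estimate = ci$estimate, se = ci$bootstrap_se)),
    risks = lapply(report$risks, function(r)
      as.list(stats::setNames(r$risk, paste0("score_", r$score)))))
}

#' @export
print.meld_run_report <- function(x, ...) {
  cat("Score-revision run report\n")
  cat("  development patients: ", x$n_dev, ", validation patients: ",
      x$n_val, "\n", sep = "")
  cat("  cross-section rows: ", x$n_cs_rows,
      ", from-registration rows: ", x$n_fr_rows, "\n", sep = "")
  cat("\nDerived score:\n")
  print(x$derived_score)
  cat("\nValidation c-indices (from cross-section):\n")
  for (nm in names(x$cindex))
    cat("  ", format(nm, width = 8), " ",
        format(round(x$cindex[[nm]]$estimate, 4)), "\n", sep = "")
  invisible(x)
}
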