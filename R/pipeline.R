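# End-to-end pipeline: simulate (or load) -> plausibility filter ->
# feature rows -> pH resampling (derivation only) -> nested CV split ->
# hyperparameter selection -> ensemble training -> threshold calibration
# -> predict-or-abstain on validation -> evaluation report + artifacts.

#' Default pipeline configuration
#'
#' A nested list mirroring the pipeline stages. One master `seed` fans
#' out to per-stage child seeds so stages can be re-run independently;
#' identical configs give byte-identical reports.
#'
#' @param generator Arguments for [bg_generator_config()] (derivation
#'   cohort; the validation cohort reuses them with
#'   `validation_n_patients` patients and its own child seed).
#' @param validation_n_patients Validation cohort size.
#' @param features `max_lag_hours`, `resample_weights`, `outer`, `inner`.
#' @param model Hyperparameter grids (`lambda_grid`, `m_grid`,
#'   `slope_grid`, `center_range`) and `select` (logical: run inner-CV
#'   selection or use `basis_m`/`basis_slope`/`lambda` directly).
#' @param uncertainty `criterion` ("rate"/"error_bound"), `rate`,
#'   `bound`, `max_patient_fraction`, `n_random` orderings for the
#'   risk-coverage curve.
#' @param evaluation `ph_edges`, `pco2_edges`, `clia_ph`, `clia_pco2`.
#' @param seed Master seed.
#' @return List of class `bg_pipeline_config`.
#' @export
bg_pipeline_config <- function(generator = list(),
                               validation_n_patients = 200L,
                               features = list(),
                               model = list(),
                               uncertainty = list(),
                               evaluation = list(),
                               seed = 1L) {
  defaults <- list(
    generator = as.list(unclass(bg_generator_config())),
    validation_n_patients = 200L,
    features = list(max_lag_hours = 24,
                    resample_weights = c(0.17, 0.54, 0.29),
                    outer = 5L, inner = 5L),
    model = list(select = TRUE,
                 lambda_grid = 10^seq(-3, 3),
                 m_grid = c(3, 5, 7),
                 slope_grid = c(5, 10, 20),
                 basis_m = 5L, basis_slope = 10, lambda = 1),
    uncertainty = list(criterion = "rate", rate = 0.25, bound = 0.1,
                       max_patient_fraction = 0.5, n_random = 20L),
    evaluation = list(ph_edges = c(7.3, 7.45), pco2_edges = c(35, 60),
                      clia_ph = 0.04, clia_pco2 = 5),
    seed = 1L)
  user <- list(generator = generator,
               validation_n_patients = validation_n_patients,
               features = features, model = model,
               uncertainty = uncertainty, evaluation = evaluation,
               seed = seed)
  cfg <- defaults
  for (sec in names(user)) {
    if (sec %in% c("validation_n_patients", "seed")) {
      cfg[[sec]] <- user[[sec]]
      next
    }
    unknown <- setdiff(names(user[[sec]]), names(defaults[[sec]]))
    if (length(unknown))
      stop_bg(sprintf("unknown %s config key(s): %s", sec,
                      paste(unknown, collapse = ", ")), "bg_config")
    cfg[[sec]][names(user[[sec]])] <- user[[sec]]
  }
  cfg$validation_n_patients <- as.integer(cfg$validation_n_patients)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "bg_pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; omitted keys take their defaults.
#'
#' @param path YAML file with any subset of the [bg_pipeline_config()]
#'   sections.
#' @return A `bg_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("generator", "validation_n_patients", "features", "model",
             "uncertainty", "evaluation", "seed")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop_bg(sprintf("unknown config section(s): %s",
                    paste(unknown, collapse = ", ")), "bg_config")
  do.call(bg_pipeline_config, raw)
}

#' Write a cohort as CSV
#'
#' One row per timestamped observation, canonical column names, with the
#' generator seed (when known) recorded in a comment-free sidecar-less
#' way: metadata travels in the config file written next to pipeline
#' outputs.
#'
#' @param cohort Cohort data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort)[, cohort_columns()], path,
                   row.names = FALSE)
  invisible(path)
}

#' Load a cohort CSV
#'
#' Validates the documented schema; missing columns are listed
#' exhaustively, unknown extra columns are preserved with a warning.
#'
#' @param path CSV with a header row of canonical cohort columns.
#' @return A `bg_cohort` data.frame.
#' @export
load_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_columns(df, cohort_columns(), sprintf("cohort file '%s'", path))
  extra <- setdiff(names(df), cohort_columns())
  if (length(extra))
    warning(sprintf("preserving unknown column(s): %s",
                    paste(extra, collapse = ", ")), call. = FALSE)
  class(df) <- c("bg_cohort", "data.frame")
  df
}

#' Write predictions as CSV
#'
#' @param predictions A `bg_predictions` data.frame (possibly augmented
#'   with truth columns).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
save_predictions <- function(predictions, path) {
  utils::write.csv(as.data.frame(predictions), path, row.names = FALSE)
  invisible(path)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop_bg(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)), "bg_stage_failure"))
}

#' Run the full estimation pipeline
#'
#' Executes every stage on synthetic cohorts and writes all artifacts
#' (resolved config, cohorts, models, predictions, evaluation report,
#' optional figures) to `out_dir`.
#'
#' @param config A [bg_pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param make_plots Write PNG figures (scatter, Bland-Altman,
#'   risk-coverage, lag curve).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the trained ensembles, predictions and
#'   the evaluation report.
#' @export
run_pipeline <- function(config = bg_pipeline_config(), out_dir,
                         make_plots = FALSE, quiet = TRUE) {
  stopifnot(inherits(config, "bg_pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  seed <- config$seed

  yaml::write_yaml(unclass(config), file.path(out_dir, "config.yaml"))

  say("simulating cohorts")
  gen <- config$generator
  gen$seed <- child_seed(seed, "derivation")
  deriv_cohort <- stage("simulate", simulate_cohort(
    do.call(bg_generator_config, gen)))
  gen$n_patients <- config$validation_n_patients
  gen$seed <- child_seed(seed, "validation")
  valid_cohort <- stage("simulate", simulate_cohort(
    do.call(bg_generator_config, gen)))

  say("filtering and building features")
  deriv_cohort <- stage("filter", plausibility_filter(deriv_cohort))$cohort
  valid_cohort <- stage("filter", plausibility_filter(valid_cohort))$cohort
  fx <- config$features
  deriv_rows <- stage("features",
                      build_feature_rows(deriv_cohort, fx$max_lag_hours))
  valid_rows <- stage("features",
                      build_feature_rows(valid_cohort, fx$max_lag_hours))

  # resampling applies to derivation training data only; validation (and
  # the calibration view of derivation) keep their natural distribution
  train_rows <- stage("resample", resample_by_ph(
    deriv_rows, target_weights = fx$resample_weights,
    seed = child_seed(seed, "resample")))

  say("splitting and selecting hyperparameters")
  plan <- stage("split", make_split_plan(train_rows, fx$outer, fx$inner,
                                         seed = child_seed(seed, "split")))
  mc <- config$model
  if (isTRUE(mc$select)) {
    sel <- stage("select", select_hyperparameters(
      train_rows, plan, target = "ph", lambda_grid = mc$lambda_grid,
      m_grid = mc$m_grid, slope_grid = mc$slope_grid))
    basis <- sel$basis
    lambda <- sel$lambda
  } else {
    sel <- NULL
    basis <- bg_default_basis(train_rows$ph_prev, mc$basis_m,
                              mc$basis_slope)
    lambda <- mc$lambda
  }

  say("training ensembles")
  ens_ph <- stage("ensemble", bg_ensemble(train_rows, plan, "ph",
                                          basis = basis, lambda = lambda))
  ens_pco2 <- stage("ensemble", bg_ensemble(train_rows, plan, "paco2",
                                            basis = basis,
                                            lambda = lambda))

  say("calibrating abstention threshold")
  uc <- config$uncertainty
  ens_ph <- stage("calibrate", calibrate_threshold(
    ens_ph, deriv_rows, criterion = uc$criterion, rate = uc$rate,
    bound = uc$bound, max_patient_fraction = uc$max_patient_fraction))

  say("predicting on validation data")
  pred_ph <- stage("predict", predict_or_abstain(ens_ph, valid_rows))
  # the pH-calibrated abstention decision is applied to the paired PCO2
  # estimate: one abstention mechanism for the blood gas as a whole
  pco2_point <- predict(ens_pco2$final_model, valid_rows)
  predictions <- data.frame(
    patient_id = valid_rows$patient_id,
    t_current = valid_rows$t_current,
    lag_hours = valid_rows$lag_hours,
    ph_truth = valid_rows$ph_t, ph_est = pred_ph$point,
    ph_uncertainty = pred_ph$uncertainty,
    ph_lower = pred_ph$lower, ph_upper = pred_ph$upper,
    ph_half_width = pred_ph$upper - pred_ph$point,
    paco2_truth = valid_rows$paco2_t, paco2_est = pco2_point,
    abstained = pred_ph$abstained,
    top1 = pred_ph$top1, top1_importance = pred_ph$top1_importance,
    top2 = pred_ph$top2, top2_importance = pred_ph$top2_importance,
    top3 = pred_ph$top3, top3_importance = pred_ph$top3_importance,
    stringsAsFactors = FALSE)

  say("evaluating")
  ev <- config$evaluation
  report <- stage("evaluate", evaluation_report(
    predictions, ph_edges = ev$ph_edges, pco2_edges = ev$pco2_edges,
    clia_ph = ev$clia_ph, clia_pco2 = ev$clia_pco2))
  rc_curve <- stage("evaluate", risk_coverage_curve(
    ens_ph, valid_rows, n_random = uc$n_random,
    seed = child_seed(seed, "evaluate")))

  write_cohort(deriv_cohort, file.path(out_dir, "derivation_cohort.csv"))
  write_cohort(valid_cohort, file.path(out_dir, "validation_cohort.csv"))
  save_predictions(predictions, file.path(out_dir, "predictions.csv"))
  write_bg_model(ens_ph$final_model, file.path(out_dir, "model_ph.json"))
  write_bg_model(ens_pco2$final_model,
                 file.path(out_dir, "model_paco2.json"))
  write_evaluation_report(report, file.path(out_dir, "report.json"))
  utils::write.csv(rc_curve, file.path(out_dir, "risk_coverage.csv"),
                   row.names = FALSE)
  utils::write.csv(plan$patients, file.path(out_dir, "split_plan.csv"),
                   row.names = FALSE)
  log_lines <- c(
    sprintf("seed: %d", seed),
    sprintf("basis: M=%d slope=%g centers=%s",
            length(basis$centers), basis$slope,
            paste(signif(basis$centers, 5), collapse = ",")),
    sprintf("lambda: %g", lambda),
    sprintf("threshold: %.10g", ens_ph$threshold),
    sprintf("abstention at calibration: %.4f",
            ens_ph$calibration$abstained_fraction))
  writeLines(log_lines, file.path(out_dir, "pipeline_log.txt"))

  if (make_plots)
    pipeline_plots(out_dir, predictions, report, rc_curve, ens_ph)

  invisible(list(ensemble_ph = ens_ph, ensemble_pco2 = ens_pco2,
                 selection = sel, predictions = predictions,
                 report = report, risk_coverage = rc_curve,
                 plan = plan))
}

pipeline_plots <- function(out_dir, predictions, report, rc_curve,
                           ens_ph) {
  est <- predictions[!predictions$abstained, ]
  plot_png <- function(name, expr) {
    grDevices::png(file.path(out_dir, name), width = 700, height = 600)
    on.exit(grDevices::dev.off())
    expr
  }
  plot_png("scatter_ph.png", {
    plot(est$ph_truth, est$ph_est, pch = 16, cex = 0.5,
         col = grDevices::rgb(0, 0, 0.7, 0.4),
         xlab = "laboratory pH", ylab = "estimated pH",
         main = "pH estimates vs laboratory values")
    graphics::abline(0, 1, col = "gray40")
    graphics::abline(v = c(7.3, 7.45), h = c(7.3, 7.45), lty = 2,
                     col = "gray70")
  })
  plot_png("bland_altman_ph.png", {
    ba <- report$bland_altman_ph
    plot((est$ph_est + est$ph_truth) / 2, est$ph_est - est$ph_truth,
         pch = 16, cex = 0.5, col = grDevices::rgb(0, 0, 0.7, 0.4),
         xlab = "mean of estimate and laboratory pH",
         ylab = "estimate - laboratory", main = "Bland-Altman, pH")
    graphics::abline(h = c(ba$mean_error, ba$lower, ba$upper),
                     lty = c(1, 2, 2))
  })
  plot_png("risk_coverage.png", {
    plot(rc_curve$rate, rc_curve$p95_random, type = "b", pch = 1,
         ylim = range(rc_curve[, -1]), xlab = "abstention rate",
         ylab = "retained p95 |pH error|",
         main = "Uncertainty-ordered vs random abstention")
    graphics::lines(rc_curve$rate, rc_curve$p95_uncertainty, type = "b",
                    pch = 16)
    graphics::legend("bottomleft", c("random", "by uncertainty"),
                     pch = c(1, 16), lty = 1)
  })
  if (!is.null(report$lag_p95)) plot_png("lag_curve.png", {
    lp <- report$lag_p95
    mid <- (lp$lower + lp$upper) / 2
    plot(mid, lp$p95, type = "b", pch = 16,
         xlab = "hours since previous blood gas",
         ylab = "p95 |pH error|", main = "Accuracy vs blood-gas age")
  })
  plot_png("pairwise_etco2.png",
           plot(ens_ph$final_model, predictor = "etco2_t"))
  invisible(NULL)
}
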