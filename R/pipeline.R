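#' Minimum-events check for a validation sample
#'
#' External validations of time-to-event models need on the order of 100
#' outcome events for stable performance estimates; the pipeline blocks runs
#' below the minimum unless explicitly overridden.
#'
#' @param data A cohort data frame.
#' @param minimum Minimum number of outcome (code 1) events, default 100.
#' @return A one-row tibble: `pass`, `n_events`, `minimum`.
#' @export
check_min_events <- function(data, minimum = 100) {
  data <- as_cohort(data)
  n_events <- sum(data$event == 1)
  tibble::tibble(pass = n_events >= minimum, n_events = n_events,
                 minimum = minimum)
}

#' Run a full external validation
#'
#' Executes the whole validation procedure against one risk model:
#' eligibility filter, complete-case filter, horizon capping, minimum-events
#' check, prognostic-index scoring, discrimination (Harrell's C and risk-group
#' survival curves), calibration (slope, mean, deciles, optional age groups)
#' and censoring-adjusted classification at the observed-risk cut-off (plus
#' the clinical threshold when the model declares one). Every metric is
#' computed twice: the main variant (competing deaths censored, Kaplan-Meier
#' observed risk) and the competing-risk variant (competing deaths recoded
#' event-free for ranking/regression, cumulative-incidence observed risk).
#' When the cohort holds no competing events the two variants coincide.
#'
#' @param cohort A cohort data frame or path to a cohort CSV.
#' @param model A `survalid_model` or path to a model-definition JSON.
#' @param n_bins Number of calibration bins (default 10).
#' @param age_bands Interior age cut points for the age-group table, or
#'   `NULL` to skip it.
#' @param min_events Minimum outcome events (default 100).
#' @param allow_below_min Set `TRUE` to run anyway below the minimum.
#' @param horizon Administrative horizon in years; defaults to the model's.
#' @return An object of class `survalid_report`.
#' @export
run_validation <- function(cohort, model, n_bins = 10,
                           age_bands = c(65, 70, 75), min_events = 100,
                           allow_below_min = FALSE, horizon = NULL) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  if (is.character(model)) model <- load_model_definition(model)
  stopifnot(inherits(model, "survalid_model"))
  horizon <- horizon %||% model$horizon
  cohort <- as_cohort(cohort)
  n_loaded <- nrow(cohort)

  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("[", what, "] ", conditionMessage(e)))
    })
  }

  eligible <- stage("eligibility", apply_eligibility(cohort, model))
  complete <- stage("complete-case", complete_case_filter(eligible, model))
  capped <- stage("horizon", cap_horizon(complete, horizon))
  minchk <- check_min_events(capped, min_events)
  if (!minchk$pass && !allow_below_min) {
    abort(sprintf(
      "[min-events] %d outcome events observed; %d required. Set allow_below_min = TRUE to override.",
      minchk$n_events, minchk$minimum))
  }

  scored <- stage("scoring", score_cohort(capped, model))
  dat <- dplyr::bind_cols(
    capped[c("time", "event", "age")],
    scored[c("pi", "cpi", "probability", "scaled_probability")])
  dat$id <- capped$id
  dat_main <- dplyr::mutate(dat, event01 = as.integer(.data$event == 1))
  dat_cr <- recode_competing_as_event_free(dat, horizon = horizon)
  dat_cr$event01 <- as.integer(dat_cr$event == 1)

  c_main <- stage("discrimination", harrells_c(
    dat_main, scaled_probability, time, event01))
  c_cr <- stage("discrimination", harrells_c_competing(
    dat, scaled_probability, time, event))

  grouped <- stage("risk-groups", risk_groups_by_pi(dat_main, pi))
  group_curves <- stage("risk-groups", km_by_group(
    grouped, risk_group, time, event01))

  slope_main <- stage("calibration", calibration_slope(
    dat_main, cpi, time, event01))
  slope_cr <- stage("calibration", calibration_slope(
    dat_cr, cpi, time, event01))
  mc_main <- stage("calibration", mean_calibration(
    dat, scaled_probability, time, event,
    reference = "km", horizon = horizon))
  mc_cr <- stage("calibration", mean_calibration(
    dat, scaled_probability, time, event,
    reference = "cif", horizon = horizon))
  dec_main <- stage("calibration", decile_calibration(
    dat, scaled_probability, time, event,
    n_bins = n_bins, reference = "km", horizon = horizon))
  dec_cr <- stage("calibration", decile_calibration(
    dat, scaled_probability, time, event,
    n_bins = n_bins, reference = "cif", horizon = horizon))
  decile_table <- dplyr::bind_rows(
    dplyr::mutate(tibble::as_tibble(dec_main), reference = "km"),
    dplyr::mutate(tibble::as_tibble(dec_cr), reference = "cif"))

  age_table <- NULL
  if (!is.null(age_bands)) {
    age_table <- stage("calibration", age_group_calibration(
      dat, scaled_probability, age, time, event,
      breaks = age_bands, horizon = horizon))
  }

  cut_main <- stage("classification", threshold_at_observed_risk(
    dat, time, event, variant = "main", horizon = horizon))
  cut_cr <- stage("classification", threshold_at_observed_risk(
    dat, time, event, variant = "competing_risk",
    horizon = horizon))
  cls_main <- stage("classification", censoring_adjusted_sn_sp(
    dat, scaled_probability, cut_main, time, event,
    variant = "main", horizon = horizon, threshold_source = "observed_risk"))
  cls_cr <- stage("classification", censoring_adjusted_sn_sp(
    dat, scaled_probability, cut_cr, time, event,
    variant = "competing_risk", horizon = horizon,
    threshold_source = "observed_risk"))

  clinical <- NULL
  if (!is.null(model$clinical_threshold)) {
    clinical <- stage("classification", clinical_threshold_classification(
      dat, probability, threshold = model$clinical_threshold,
      time = time, event = event, variant = "main",
      horizon = horizon))
  }

  results <- tibble::tibble(
    variant = c("main", "competing_risk"),
    c_index = c(c_main$c_index, c_cr$c_index),
    c_conf_low = c(c_main$conf_low, c_cr$conf_low),
    c_conf_high = c(c_main$conf_high, c_cr$conf_high),
    calibration_slope = c(slope_main$slope, slope_cr$slope),
    slope_conf_low = c(slope_main$conf_low, slope_cr$conf_low),
    slope_conf_high = c(slope_main$conf_high, slope_cr$conf_high),
    slope_p_vs_1 = c(slope_main$p_vs_1, slope_cr$p_vs_1),
    mean_calibration = c(mc_main$ratio, mc_cr$ratio),
    cutoff_pct = 100 * c(cut_main, cut_cr),
    sensitivity_pct = 100 * c(cls_main$sensitivity, cls_cr$sensitivity),
    specificity_pct = 100 * c(cls_main$specificity, cls_cr$specificity),
    observed_risk_pct = 100 * c(mc_main$observed_risk, mc_cr$observed_risk))

  report <- structure(
    list(
      model_name = model$name, outcome_label = model$outcome_label,
      horizon = horizon,
      counts = tibble::tibble(
        stage = c("loaded", "eligible", "complete_case"),
        n = c(n_loaded, nrow(eligible), nrow(capped))),
      n = nrow(capped), n_events = sum(capped$event == 1),
      n_competing = sum(capped$event == 2),
      min_events = minchk,
      results = results,
      clinical = clinical,
      decile_table = decile_table,
      age_table = age_table,
      risk_group_curves = group_curves,
      risk_group_cuts = attr(grouped, "cut_points"),
      predictions = scored,
      provenance = list(
        cohort_hash = rlang::hash(as.data.frame(cohort)),
        model_hash = rlang::hash(unclass(model)),
        n_bins = n_bins, age_bands = age_bands, min_events = min_events,
        horizon = horizon,
        package_version = as.character(utils::packageVersion("survalid")))),
    class = "survalid_report")
  report
}

#' @export
print.survalid_report <- function(x, ...) {
  cat("<survalid_report> model:", x$model_name,
      " outcome:", x$outcome_label, "\n")
  cat(sprintf("  n = %d (of %d loaded), events = %d, competing deaths = %d, horizon = %gy\n",
              x$n, x$counts$n[1], x$n_events, x$n_competing, x$horizon))
  r <- x$results
  for (i in seq_len(nrow(r))) {
    cat(sprintf("  [%s]\n", r$variant[i]))
    cat(sprintf("    Harrell's C      %.4f [%.4f-%.4f]\n",
                r$c_index[i], r$c_conf_low[i], r$c_conf_high[i]))
    cat(sprintf("    Calibration slope %.2f [%.2f-%.2f], p vs 1 = %.4g\n",
                r$calibration_slope[i], r$slope_conf_low[i],
                r$slope_conf_high[i], r$slope_p_vs_1[i]))
    cat(sprintf("    Mean calibration  %.2f\n", r$mean_calibration[i]))
    cat(sprintf("    Cut-off %.2f%%: Sn %.0f%%, Sp %.0f%% (observed risk %.1f%%)\n",
                r$cutoff_pct[i], r$sensitivity_pct[i], r$specificity_pct[i],
                r$observed_risk_pct[i]))
  }
  if (!is.null(x$clinical)) {
    cat(sprintf("  clinical threshold %.1f%%: Sn %.0f%%, Sp %.0f%%\n",
                100 * x$clinical$threshold, 100 * x$clinical$sensitivity,
                100 * x$clinical$specificity))
  }
  invisible(x)
}

#' @export
tidy.survalid_report <- function(x, ...) {
  tidyr::pivot_longer(x$results, -"variant", names_to = "metric",
                      values_to = "value")
}

#' @export
glance.survalid_report <- function(x, ...) {
  main <- x$results[x$results$variant == "main", ]
  tibble::tibble(
    model = x$model_name, n = x$n, n_events = x$n_events,
    n_competing = x$n_competing, c_index = main$c_index,
    calibration_slope = main$calibration_slope,
    mean_calibration = main$mean_calibration,
    sensitivity_pct = main$sensitivity_pct,
    specificity_pct = main$specificity_pct,
    observed_risk_pct = main$observed_risk_pct)
}

#' Write a validation report to disk
#'
#' Emits `report.json` plus tidy CSV sub-tables (`deciles.csv`,
#' `age_groups.csv`, `risk_group_km.csv`, `predictions.csv`). Output is
#' deterministic: identical inputs produce byte-identical files.
#'
#' @param report A `survalid_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the path of the JSON report.
#' @export
write_validation_report <- function(report, dir) {
  stopifnot(inherits(report, "survalid_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  json <- list(
    model = report$model_name, outcome = report$outcome_label,
    horizon = report$horizon,
    counts = as.data.frame(report$counts),
    n = report$n, n_events = report$n_events,
    n_competing = report$n_competing,
    results = as.data.frame(report$results),
    clinical = if (!is.null(report$clinical)) as.data.frame(report$clinical),
    risk_group_cuts = as.list(report$risk_group_cuts),
    provenance = report$provenance)
  path <- file.path(dir, "report.json")
  jsonlite::write_json(json, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  utils::write.csv(as.data.frame(report$decile_table),
                   file.path(dir, "deciles.csv"), row.names = FALSE)
  if (!is.null(report$age_table)) {
    utils::write.csv(as.data.frame(report$age_table),
                     file.path(dir, "age_groups.csv"), row.names = FALSE)
  }
  utils::write.csv(as.data.frame(report$risk_group_curves),
                   file.path(dir, "risk_group_km.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(report$predictions),
                   file.path(dir, "predictions.csv"), row.names = FALSE)
  invisible(path)
}

#' Head-to-head comparison of several models on a common sub-sample
#'
#' Applies the union of all models' eligibility exclusions and the union of
#' their complete-case requirements to form one common sub-sample, validates
#' each model on it, and tabulates agreement: subjects are binned by deciles
#' of the across-model mean scaled prediction and each model's mean
#' prediction is reported per bin, together with per-subject predictions for
#' pairwise scatter displays.
#'
#' @param cohort A cohort data frame or CSV path.
#' @param models List of `survalid_model`s (or paths), at least two.
#' @param n_bins Number of agreement bins (default 10).
#' @param ... Passed to [run_validation()].
#' @return A list of class `survalid_head2head`: `common_n`, `reports`
#'   (named list), `agreement` (tibble), `predictions` (wide tibble).
#' @export
run_head_to_head <- function(cohort, models, n_bins = 10, ...) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  models <- lapply(models, function(m) {
    if (is.character(m)) load_model_definition(m) else m
  })
  if (length(models) < 2) abort("Head-to-head needs at least two models.")
  names(models) <- vapply(models, `[[`, "", "name")
  common <- as_cohort(cohort)
  for (m in models) common <- apply_eligibility(common, m)
  for (m in models) common <- complete_case_filter(common, m)
  if (nrow(common) == 0) abort("The common eligible sub-sample is empty.")
  reports <- lapply(models, function(m) run_validation(common, m, ...))
  preds <- tibble::tibble(id = common$id)
  for (m in models) {
    preds[[m$name]] <- score_cohort(common, m)$scaled_probability
  }
  mean_pred <- rowMeans(as.matrix(preds[, -1, drop = FALSE]))
  bin <- prediction_bins(mean_pred, n_bins)
  agreement <- dplyr::bind_rows(lapply(seq_len(n_bins), function(b) {
    sel <- bin == b
    row <- tibble::tibble(bin = b, n = sum(sel),
                          mean_prediction = mean(mean_pred[sel]))
    for (nm in names(models)) row[[nm]] <- mean(preds[[nm]][sel])
    row
  }))
  structure(
    list(common_n = nrow(common), reports = reports, agreement = agreement,
         predictions = preds),
    class = "survalid_head2head")
}

#' @export
print.survalid_head2head <- function(x, ...) {
  cat("<survalid_head2head>", length(x$reports),
      "models on a common sub-sample of", x$common_n, "subjects\n")
  for (r in x$reports) {
    g <- glance(r)
    cat(sprintf("  %-24s C %.4f  slope %.2f  mean-cal %.2f\n",
                g$model, g$c_index, g$calibration_slope, g$mean_calibration))
  }
  invisible(x)
}
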