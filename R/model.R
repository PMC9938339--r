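#' Declarative risk-model definitions
#'
#' A risk model is described declaratively: an ordered list of predictors,
#' each with a transform, a published coefficient and a published centring
#' mean (on the transformed scale); the published baseline survivor function
#' at the horizon; and, for composite-outcome tools, an outcome fraction that
#' rescales composite predicted probabilities to the outcome of interest.
#' The 10-year predicted probability for a subject is
#' `P = 1 - S0 ^ exp(CPI)` where `CPI` is the centred prognostic index.
#'
#' @param name Model name.
#' @param predictors List of predictor specs; each a list with `name`,
#'   `transform` (see Details), `coefficient` and `mean`.
#' @param baseline_survival Survivor probability at the horizon for a subject
#'   at the centring means; in (0, 1].
#' @param horizon Prediction horizon in years (> 0).
#' @param outcome_fraction Proportion of composite events that are the
#'   outcome of interest; in (0, 1], 1 for outcome-specific tools.
#' @param outcome_label Free-text outcome description.
#' @param eligibility List of exclusion predicates, each a list with
#'   `covariate` and optionally `exclude_when` (default `TRUE`) and `label`.
#' @param clinical_threshold Optional conventional intervention threshold on
#'   the unscaled composite probability scale.
#'
#' @details Transforms may be the strings `"identity"`, `"log"`,
#'   `"indicator"`, or a list: `list(type = "indicator", equals = v)`,
#'   `list(type = "onehot", level = "x")` for categorical one-hot terms, or
#'   `list(type = "product", terms = c("a", "b"))` for interaction terms
#'   (product of the named raw covariates; the predictor's own `name` is then
#'   just a label).
#'
#' @return An object of class `survalid_model`.
#' @export
risk_model <- function(name, predictors, baseline_survival, horizon = 10,
                       outcome_fraction = 1, outcome_label = NULL,
                       eligibility = list(), clinical_threshold = NULL) {
  if (!is.character(name) || length(name) != 1) abort("`name` must be a string.")
  if (!is.numeric(baseline_survival) || length(baseline_survival) != 1 ||
      is.na(baseline_survival) || baseline_survival <= 0 || baseline_survival > 1) {
    abort("`baseline_survival` must be a single number in (0, 1].")
  }
  if (!is.numeric(horizon) || length(horizon) != 1 || horizon <= 0) {
    abort("`horizon` must be a single positive number.")
  }
  if (!is.numeric(outcome_fraction) || length(outcome_fraction) != 1 ||
      is.na(outcome_fraction) || outcome_fraction <= 0 || outcome_fraction > 1) {
    abort("`outcome_fraction` must be a single number in (0, 1].")
  }
  if (!is.list(predictors) || length(predictors) == 0) {
    abort("`predictors` must be a non-empty list.")
  }
  predictors <- lapply(seq_along(predictors), function(i) {
    p <- predictors[[i]]
    for (field in c("name", "coefficient", "mean")) {
      if (is.null(p[[field]])) {
        abort(paste0("Predictor ", i, " is missing field `", field, "`."))
      }
    }
    if (!is.numeric(p$coefficient) || !is.finite(p$coefficient)) {
      abort(paste0("Predictor `", p$name, "` has a non-numeric coefficient."))
    }
    if (!is.numeric(p$mean) || !is.finite(p$mean)) {
      abort(paste0("Predictor `", p$name, "` has a non-numeric centring mean."))
    }
    p$transform <- normalise_transform(p$transform %||% "identity", p$name)
    p
  })
  eligibility <- lapply(seq_along(eligibility), function(i) {
    e <- eligibility[[i]]
    if (is.null(e$covariate)) {
      abort(paste0("Eligibility predicate ", i, " is missing field `covariate`."))
    }
    e$exclude_when <- e$exclude_when %||% TRUE
    e$label <- e$label %||% e$covariate
    e
  })
  if (!is.null(clinical_threshold)) {
    if (!is.numeric(clinical_threshold) || clinical_threshold <= 0 ||
        clinical_threshold >= 1) {
      abort("`clinical_threshold` must lie in (0, 1).")
    }
  }
  structure(
    list(name = name, outcome_label = outcome_label %||% name,
         horizon = horizon, baseline_survival = baseline_survival,
         outcome_fraction = outcome_fraction, predictors = predictors,
         eligibility = eligibility, clinical_threshold = clinical_threshold),
    class = "survalid_model")
}

normalise_transform <- function(tr, pname) {
  if (is.character(tr) && length(tr) == 1) tr <- list(type = tr)
  if (!is.list(tr) || is.null(tr$type)) {
    abort(paste0("Predictor `", pname, "` has an invalid transform spec."))
  }
  if (!tr$type %in% c("identity", "log", "indicator", "onehot", "product")) {
    abort(paste0("Predictor `", pname, "` uses unknown transform `", tr$type, "`."))
  }
  if (tr$type == "onehot" && is.null(tr$level)) {
    abort(paste0("Predictor `", pname, "`: onehot transform needs a `level`."))
  }
  if (tr$type == "product" &&
      (is.null(tr$terms) || length(tr$terms) < 2)) {
    abort(paste0("Predictor `", pname,
                 "`: product transform needs at least two `terms`."))
  }
  tr
}

#' Load a risk-model definition from JSON
#'
#' @param path Path to a JSON model-definition file (see [risk_model()] for
#'   the schema).
#' @return A validated `survalid_model`.
#' @export
load_model_definition <- function(path) {
  if (!file.exists(path)) abort(paste0("Model file not found: ", path))
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (field in c("name", "baseline_survival", "predictors")) {
    if (is.null(raw[[field]])) {
      abort(paste0("Model definition `", path, "` is missing field `", field, "`."))
    }
  }
  preds <- lapply(raw$predictors, function(p) {
    if (!is.null(p$transform) && is.list(p$transform) &&
        !is.null(p$transform$terms)) {
      p$transform$terms <- unlist(p$transform$terms)
    }
    p
  })
  risk_model(
    name = raw$name,
    outcome_label = raw$outcome_label,
    horizon = raw$horizon %||% 10,
    baseline_survival = raw$baseline_survival,
    outcome_fraction = raw$outcome_fraction %||% 1,
    predictors = preds,
    eligibility = raw$eligibility %||% list(),
    clinical_threshold = raw$clinical_threshold
  )
}

#' @export
print.survalid_model <- function(x, ...) {
  cat("<survalid_model> ", x$name, "\n", sep = "")
  cat("  outcome: ", x$outcome_label,
      "  horizon: ", x$horizon, "y\n", sep = "")
  cat("  baseline survival S0(", x$horizon, ") = ", x$baseline_survival,
      ";  outcome fraction = ", x$outcome_fraction, "\n", sep = "")
  cat("  predictors (", length(x$predictors), "):\n", sep = "")
  for (p in x$predictors) {
    cat(sprintf("    %-20s %-10s beta = %+.4f  mean = %.4f\n",
                p$name, p$transform$type, p$coefficient, p$mean))
  }
  if (length(x$eligibility) > 0) {
    cat("  exclusions: ",
        paste(vapply(x$eligibility, `[[`, "", "label"), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Covariates a model reads
#'
#' Unique raw covariate names a model's predictors and transforms reference;
#' this is the set the complete-case rule applies to.
#'
#' @param model A `survalid_model`.
#' @return Character vector of covariate names.
#' @export
model_covariates <- function(model) {
  stopifnot(inherits(model, "survalid_model"))
  unique(unlist(lapply(model$predictors, function(p) {
    if (p$transform$type == "product") p$transform$terms else p$name
  })))
}

# Transformed value of one predictor for each row of `data`; NA propagates.
transform_column <- function(p, data) {
  tr <- p$transform
  if (tr$type == "product") {
    miss <- setdiff(tr$terms, names(data))
    if (length(miss) > 0) return(rep(NA_real_, nrow(data)))
    out <- rep(1, nrow(data))
    for (term in tr$terms) out <- out * as.numeric(data[[term]])
    return(out)
  }
  if (!p$name %in% names(data)) return(rep(NA_real_, nrow(data)))
  x <- data[[p$name]]
  switch(tr$type,
    identity = as.numeric(x),
    log = {
      v <- as.numeric(x)
      bad <- !is.na(v) & v <= 0
      if (any(bad)) {
        abort(paste0("Predictor `", p$name,
                     "`: log transform applied to non-positive value(s)."))
      }
      log(v)
    },
    indicator = {
      eq <- tr$equals %||% TRUE
      ifelse(is.na(x), NA_real_, as.numeric(x == eq))
    },
    onehot = ifelse(is.na(x), NA_real_, as.numeric(as.character(x) == tr$level))
  )
}

# n x p matrix of transformed predictor values, one column per predictor.
design_matrix <- function(model, data) {
  cols <- lapply(model$predictors, transform_column, data = data)
  mat <- do.call(cbind, cols)
  colnames(mat) <- vapply(model$predictors, `[[`, "", "name")
  mat
}

#' Prognostic index of one subject
#'
#' The linear predictor `PI = sum_j beta_j * t_j(x_j)` of the model evaluated
#' on a single covariate map. A missing covariate is an error: the
#' complete-case rule is enforced explicitly, never by silent imputation.
#'
#' @param model A `survalid_model`.
#' @param covariates Named list (or one-row data frame) of covariate values.
#' @return The prognostic index (a single number).
#' @export
compute_prognostic_index <- function(model, covariates) {
  stopifnot(inherits(model, "survalid_model"))
  if (is.list(covariates) && !is.data.frame(covariates)) {
    covariates <- tibble::as_tibble(covariates)
  }
  if (nrow(covariates) != 1) abort("`covariates` must describe one subject.")
  mat <- design_matrix(model, covariates)
  if (anyNA(mat)) {
    miss <- colnames(mat)[is.na(mat[1, ])]
    abort(paste0("Missing covariate value(s) for predictor(s): ",
                 paste(miss, collapse = ", "),
                 ". Complete cases are required; no imputation is performed."))
  }
  betas <- vapply(model$predictors, `[[`, 0, "coefficient")
  drop(mat %*% betas)
}

#' Centre a prognostic index at the published means
#'
#' `CPI = PI - sum_j beta_j * m_j` with `m_j` the published per-predictor
#' mean on the transformed scale.
#'
#' @param model A `survalid_model`.
#' @param pi Prognostic index value(s).
#' @return Centred prognostic index, same length as `pi`.
#' @export
centre_prognostic_index <- function(model, pi) {
  stopifnot(inherits(model, "survalid_model"))
  betas <- vapply(model$predictors, `[[`, 0, "coefficient")
  means <- vapply(model$predictors, `[[`, 0, "mean")
  pi - sum(betas * means)
}

#' Predicted event probability at the horizon
#'
#' `P = 1 - S0 ^ exp(CPI)` with `S0` the published baseline survivor
#' function at the horizon. An overflowing `exp(CPI)` saturates the
#' probability just below 1 with a warning, since an extreme prognostic index
#' almost always signals a scoring bug upstream.
#'
#' @param model A `survalid_model`.
#' @param cpi Centred prognostic index value(s).
#' @return Probabilities in `[0, 1)`.
#' @export
predict_event_probability <- function(model, cpi) {
  stopifnot(inherits(model, "survalid_model"))
  s0 <- model$baseline_survival
  p <- 1 - s0^exp(cpi)
  high <- is.finite(cpi) & p >= 1
  if (any(high) && s0 < 1) {
    warn(paste0(sum(high), " subject(s) have exp(CPI) large enough to ",
                "saturate the predicted probability; check the scoring inputs."))
    p[high] <- 1 - .Machine$double.eps
  }
  p
}

#' Rescale a composite predicted probability to the outcome of interest
#'
#' Multiplies by the model's outcome fraction (the proportion of all
#' composite events that are the outcome); the identity for outcome-specific
#' tools whose fraction is 1.
#'
#' @param model A `survalid_model`.
#' @param p Probabilities in `[0, 1]`.
#' @return Scaled probabilities.
#' @export
scale_to_outcome <- function(model, p) {
  stopifnot(inherits(model, "survalid_model"))
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("`p` must lie in [0, 1].")
  p * model$outcome_fraction
}

#' Score a cohort with a risk model
#'
#' Computes, per subject: the prognostic index (PI), the centred prognostic
#' index (CPI), the predicted probability of the model's (possibly composite)
#' outcome at the horizon, and the outcome-scaled probability.
#'
#' @param data A cohort data frame (complete cases for the model's
#'   covariates; see [complete_case_filter()]).
#' @param model A `survalid_model`.
#' @return A tibble with columns `id`, `pi`, `cpi`, `probability`,
#'   `scaled_probability`.
#' @export
score_cohort <- function(data, model) {
  data <- as_cohort(data)
  stopifnot(inherits(model, "survalid_model"))
  mat <- design_matrix(model, data)
  if (anyNA(mat)) {
    bad <- colnames(mat)[colSums(is.na(mat)) > 0]
    abort(paste0("Missing covariate value(s) for predictor(s): ",
                 paste(bad, collapse = ", "),
                 ". Apply complete_case_filter() before scoring."))
  }
  betas <- vapply(model$predictors, `[[`, 0, "coefficient")
  pi <- drop(mat %*% betas)
  cpi <- centre_prognostic_index(model, pi)
  p <- predict_event_probability(model, cpi)
  tibble::tibble(
    id = data$id, pi = pi, cpi = cpi, probability = p,
    scaled_probability = scale_to_outcome(model, p)
  )
}

#' Apply a model's eligibility exclusions
#'
#' Drops subjects flagged by any of the model's exclusion predicates (for
#' example a history of stroke or statin use) and reports how many each
#' predicate excluded. Idempotent.
#'
#' @param data A cohort data frame.
#' @param model A `survalid_model`.
#' @return The eligible subset as a tibble, with an `exclusions` attribute
#'   holding per-predicate counts.
#' @export
apply_eligibility <- function(data, model) {
  data <- as_cohort(data)
  stopifnot(inherits(model, "survalid_model"))
  excluded <- rep(FALSE, nrow(data))
  counts <- tibble::tibble(predicate = character(), excluded = integer())
  for (e in model$eligibility) {
    if (!e$covariate %in% names(data)) {
      abort(paste0("Eligibility predicate `", e$label,
                   "` references absent covariate `", e$covariate, "`."))
    }
    hit <- !is.na(data[[e$covariate]]) & data[[e$covariate]] == e$exclude_when
    counts <- dplyr::bind_rows(
      counts, tibble::tibble(predicate = e$label, excluded = sum(hit)))
    excluded <- excluded | hit
  }
  if (nrow(counts) > 0 && sum(counts$excluded) > 0) {
    inform(paste0("Eligibility: excluded ", sum(excluded), " of ", nrow(data),
                  " subjects (",
                  paste(sprintf("%s: %d", counts$predicate, counts$excluded),
                        collapse = "; "), ")."))
  }
  out <- data[!excluded, , drop = FALSE]
  attr(out, "exclusions") <- counts
  out
}

#' Complete-case filter for a model's covariates
#'
#' Drops subjects with a missing value in any covariate the model reads and
#' reports the missingness fraction; warns when more than 15% of subjects
#' are dropped. Idempotent; never imputes.
#'
#' @param data A cohort data frame.
#' @param model A `survalid_model`.
#' @return The complete-case subset as a tibble, with a `missingness`
#'   attribute holding per-covariate missing counts.
#' @export
complete_case_filter <- function(data, model) {
  data <- as_cohort(data)
  stopifnot(inherits(model, "survalid_model"))
  needed <- model_covariates(model)
  absent <- setdiff(needed, names(data))
  if (length(absent) > 0) {
    abort(paste0("Cohort lacks covariate column(s) required by the model: ",
                 paste(absent, collapse = ", "), "."))
  }
  na_by_cov <- vapply(needed, function(v) sum(is.na(data[[v]])), 0L)
  any_missing <- Reduce(`|`, lapply(needed, function(v) is.na(data[[v]])))
  frac <- mean(any_missing)
  if (frac > 0) {
    inform(sprintf("Complete-case filter: dropped %d of %d subjects (%.1f%% missing).",
                   sum(any_missing), nrow(data), 100 * frac))
  }
  if (frac > 0.15) {
    warn(sprintf("Missingness is %.1f%%, above 15%%; complete-case results may be fragile.",
                 100 * frac))
  }
  out <- data[!any_missing, , drop = FALSE]
  attr(out, "missingness") <- tibble::tibble(
    covariate = needed, n_missing = unname(na_by_cov))
  attr(out, "missing_fraction") <- frac
  out
}
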