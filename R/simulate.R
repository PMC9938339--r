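#' Scenario configuration for synthetic older-cohort generation
#'
#' Describes a cohort of older men with cause-specific stroke and non-stroke
#' death hazards driven by a configurable true model, so every validation
#' stage has a known-truth oracle. The defaults emulate the structure of a
#' population-based cohort of men aged 60-79 followed for up to 10 years:
#' roughly 10% experience the stroke outcome and two-to-three times as many
#' die of other causes, with competing mortality rising steeply with age.
#'
#' @param n Number of subjects.
#' @param seed Integer seed; generation is bit-reproducible given
#'   `(config, seed)`.
#' @param age_range,age_mean,age_sd Truncated-normal age distribution
#'   (years).
#' @param covariates Named list of covariate specs. Each spec is a list with
#'   `dist` in `"normal"`, `"lognormal"`, `"bernoulli"` and parameters
#'   (`mean`/`sd` plus optional `age_slope` per year; `meanlog`/`sdlog`;
#'   `prob` plus optional `age_logit_slope`).
#' @param stroke_model,death_model Cause-specific hazard models: lists with
#'   `baseline_rate` (events/year at the centring values), `shape` (Weibull
#'   shape; 1 = exponential), `coefficients` (named log-hazard ratios; the
#'   name `age` refers to the age column) and `centring` (named values the
#'   linear predictor is centred at). `death_model = NULL` disables competing
#'   deaths.
#' @param dropout_fraction Fraction of subjects with a uniform(0, horizon)
#'   dropout time, independent of covariates; all others are administratively
#'   censored at the horizon.
#' @param horizon Administrative horizon in years.
#' @param slope_multiplier,baseline_inflation,top_tail_inflation
#'   Miscalibration knobs (all default 1 = the identity scenario): the stroke
#'   linear predictor is multiplied by `1/slope_multiplier` at generation (so
#'   a validation of the unmodified model recovers a calibration slope of
#'   about `1/slope_multiplier`); the stroke baseline hazard is divided by
#'   `baseline_inflation` (so the unmodified model over-predicts by about
#'   that factor); and the stroke hazard of subjects above the
#'   `top_tail_quantile` of the linear predictor is multiplied by
#'   `top_tail_inflation` (below 1 manufactures top-decile over-estimation).
#' @param top_tail_quantile Quantile of the stroke linear predictor above
#'   which `top_tail_inflation` applies.
#' @return An object of class `survalid_scenario`.
#' @export
scenario_config <- function(n = 4000, seed = 1,
                            age_range = c(60, 79), age_mean = 68, age_sd = 5.5,
                            covariates = default_covariate_specs(),
                            stroke_model = default_stroke_model(),
                            death_model = default_death_model(),
                            dropout_fraction = 0.04, horizon = 10,
                            slope_multiplier = 1, baseline_inflation = 1,
                            top_tail_inflation = 1, top_tail_quantile = 0.7) {
  if (n <= 0) abort("`n` must be positive.")
  if (dropout_fraction < 0 || dropout_fraction >= 1) {
    abort("`dropout_fraction` must lie in [0, 1).")
  }
  for (knob in c(slope_multiplier, baseline_inflation, top_tail_inflation)) {
    if (!is.numeric(knob) || knob <= 0) abort("Miscalibration knobs must be positive.")
  }
  check_hazard_model <- function(m, what) {
    if (is.null(m)) return(invisible())
    if (is.null(m$baseline_rate) || m$baseline_rate < 0) {
      abort(paste0(what, ": `baseline_rate` must be non-negative."))
    }
    m$shape <- m$shape %||% 1
    if (m$shape <= 0) abort(paste0(what, ": `shape` must be positive."))
    extra <- setdiff(setdiff(names(m$coefficients), "age"), names(covariates))
    if (length(extra) > 0) {
      abort(paste0(what, " references unknown covariate(s): ",
                   paste(extra, collapse = ", "), "."))
    }
    miss <- setdiff(names(m$coefficients), names(m$centring))
    if (length(miss) > 0) {
      abort(paste0(what, " lacks centring value(s) for: ",
                   paste(miss, collapse = ", "), "."))
    }
    m
  }
  stroke_model <- check_hazard_model(stroke_model, "stroke_model")
  death_model <- check_hazard_model(death_model, "death_model")
  structure(
    list(n = as.integer(n), seed = as.integer(seed), age_range = age_range,
         age_mean = age_mean, age_sd = age_sd, covariates = covariates,
         stroke_model = stroke_model, death_model = death_model,
         dropout_fraction = dropout_fraction, horizon = horizon,
         slope_multiplier = slope_multiplier,
         baseline_inflation = baseline_inflation,
         top_tail_inflation = top_tail_inflation,
         top_tail_quantile = top_tail_quantile),
    class = "survalid_scenario")
}

#' @rdname scenario_config
#' @export
default_covariate_specs <- function() {
  list(
    sbp = list(dist = "normal", mean = 150, sd = 22, age_slope = 0.5),
    chol_hdl_ratio = list(dist = "lognormal", meanlog = log(4.4), sdlog = 0.25),
    bmi = list(dist = "normal", mean = 26.8, sd = 3.7),
    smoker = list(dist = "bernoulli", prob = 0.12, age_logit_slope = -0.03),
    diabetes = list(dist = "bernoulli", prob = 0.09),
    af = list(dist = "bernoulli", prob = 0.06, age_logit_slope = 0.05),
    bp_treatment = list(dist = "bernoulli", prob = 0.30, age_logit_slope = 0.04),
    prior_stroke = list(dist = "bernoulli", prob = 0.04),
    prior_tia = list(dist = "bernoulli", prob = 0.03),
    chd = list(dist = "bernoulli", prob = 0.17, age_logit_slope = 0.03),
    statin_use = list(dist = "bernoulli", prob = 0.08),
    anticoagulant_use = list(dist = "bernoulli", prob = 0.03)
  )
}

#' @rdname scenario_config
#' @export
default_stroke_model <- function() {
  list(baseline_rate = 0.011, shape = 1,
       coefficients = c(age = 0.06, sbp = 0.012, smoker = 0.35,
                        diabetes = 0.30, af = 0.55, bp_treatment = 0.20),
       centring = c(age = 68, sbp = 150, smoker = 0.12, diabetes = 0.09,
                    af = 0.06, bp_treatment = 0.30))
}

#' @rdname scenario_config
#' @export
default_death_model <- function() {
  list(baseline_rate = 0.026, shape = 1,
       coefficients = c(age = 0.095, smoker = 0.60, diabetes = 0.35),
       centring = c(age = 68, smoker = 0.12, diabetes = 0.09))
}

#' @export
print.survalid_scenario <- function(x, ...) {
  cat("<survalid_scenario> n =", x$n, " seed =", x$seed, "\n")
  cat("  age ~ trunc-normal(", x$age_mean, ",", x$age_sd, ") on [",
      x$age_range[1], ",", x$age_range[2], "]\n")
  cat("  covariates:", paste(names(x$covariates), collapse = ", "), "\n")
  cat("  stroke baseline rate:", x$stroke_model$baseline_rate, "/y, shape",
      x$stroke_model$shape, "\n")
  if (!is.null(x$death_model)) {
    cat("  competing-death baseline rate:", x$death_model$baseline_rate,
        "/y, shape", x$death_model$shape, "\n")
  } else {
    cat("  no competing deaths\n")
  }
  cat("  dropout:", x$dropout_fraction, " horizon:", x$horizon, "y\n")
  knobs <- c(slope_multiplier = x$slope_multiplier,
             baseline_inflation = x$baseline_inflation,
             top_tail_inflation = x$top_tail_inflation)
  if (any(knobs != 1)) {
    cat("  miscalibration knobs:",
        paste(names(knobs)[knobs != 1], knobs[knobs != 1],
              sep = " = ", collapse = ", "), "\n")
  }
  invisible(x)
}

# Centred linear predictor of a hazard model over cohort rows.
hazard_lp <- function(model, data) {
  lp <- rep(0, nrow(data))
  for (nm in names(model$coefficients)) {
    lp <- lp + model$coefficients[[nm]] *
      (as.numeric(data[[nm]]) - model$centring[[nm]])
  }
  lp
}

# Subject-level stroke/death rates with the miscalibration knobs applied.
scenario_rates <- function(config, data) {
  lp1 <- hazard_lp(config$stroke_model, data)
  tail_mult <- rep(1, nrow(data))
  if (config$top_tail_inflation != 1) {
    thr <- stats::quantile(lp1, config$top_tail_quantile, names = FALSE)
    tail_mult[lp1 > thr] <- config$top_tail_inflation
  }
  rate1 <- config$stroke_model$baseline_rate / config$baseline_inflation *
    exp(lp1 / config$slope_multiplier) * tail_mult
  if (!is.null(config$death_model)) {
    lp2 <- hazard_lp(config$death_model, data)
    rate2 <- config$death_model$baseline_rate * exp(lp2)
  } else {
    lp2 <- rep(0, nrow(data))
    rate2 <- rep(0, nrow(data))
  }
  list(lp1 = lp1, lp2 = lp2, rate1 = rate1, rate2 = rate2,
       shape1 = config$stroke_model$shape,
       shape2 = if (is.null(config$death_model)) 1 else config$death_model$shape)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws covariates, latent cause-specific event times (inverse transform
#' from the configured Weibull/exponential cause-specific hazards; the
#' observed cause is the earlier latent time) and censoring (independent
#' uniform dropout plus administrative censoring at the horizon). The latent
#' truth — linear predictors, latent event times, the analytic 10-year
#' cause-1 cumulative incidence and the latent 10-year status — travels in a
#' `truth` attribute so the validation pipeline cannot accidentally consume
#' it.
#'
#' @param config A [scenario_config()].
#' @param seed Overrides `config$seed` when given.
#' @return A cohort tibble (`id`, `time`, `event`, `age`, covariates) of
#'   class `survalid_cohort` with attribute `truth`.
#' @export
generate_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "survalid_scenario"))
  set.seed(seed %||% config$seed)
  n <- config$n
  # age: truncated normal via inverse-CDF
  lo <- stats::pnorm((config$age_range[1] - config$age_mean) / config$age_sd)
  hi <- stats::pnorm((config$age_range[2] - config$age_mean) / config$age_sd)
  age <- config$age_mean +
    config$age_sd * stats::qnorm(stats::runif(n, lo, hi))
  data <- tibble::tibble(id = sprintf("S%05d", seq_len(n)), age = age)
  for (nm in names(config$covariates)) {
    sp <- config$covariates[[nm]]
    data[[nm]] <- switch(sp$dist,
      normal = sp$mean + (sp$age_slope %||% 0) * (age - config$age_mean) +
        sp$sd * stats::rnorm(n),
      lognormal = stats::rlnorm(
        n, sp$meanlog + (sp$age_slope %||% 0) * (age - config$age_mean),
        sp$sdlog),
      bernoulli = {
        pr <- stats::plogis(stats::qlogis(sp$prob) +
                              (sp$age_logit_slope %||% 0) * (age - config$age_mean))
        stats::rbinom(n, 1L, pr)
      },
      abort(paste0("Covariate `", nm, "` has unknown distribution `", sp$dist, "`."))
    )
  }
  r <- scenario_rates(config, data)
  draw_time <- function(rate, shape) {
    e <- stats::rexp(n)
    tt <- ifelse(rate > 0, (e / rate)^(1 / shape), Inf)
    tt
  }
  t1 <- draw_time(r$rate1, r$shape1)
  t2 <- draw_time(r$rate2, r$shape2)
  has_drop <- stats::rbinom(n, 1L, config$dropout_fraction) == 1L
  cdrop <- ifelse(has_drop, stats::runif(n, 0, config$horizon), Inf)
  cens <- pmin(cdrop, config$horizon)
  tobs <- pmin(t1, t2, cens)
  event <- integer(n)
  event[t1 <= tobs & t1 <= t2] <- 1L
  event[t2 <= tobs & t2 < t1] <- 2L
  event[cens < pmin(t1, t2)] <- 0L
  tobs <- pmax(tobs, .Machine$double.eps) # guard against a zero draw
  out <- data
  out$time <- tobs
  out$event <- event
  out <- dplyr::relocate(out, "id", "time", "event", "age")
  latent_min <- pmin(t1, t2)
  truth <- tibble::tibble(
    id = data$id, true_lp_stroke = r$lp1, true_lp_death = r$lp2,
    true_t_stroke = t1, true_t_death = t2,
    true_cif10 = cif_closed_form(r, config$horizon),
    true_status_10y = dplyr::case_when(
      latent_min > config$horizon ~ 0L,
      t1 <= t2 ~ 1L, .default = 2L),
    true_net_stroke_10y = as.integer(t1 <= config$horizon))
  attr(out, "truth") <- truth
  class(out) <- c("survalid_cohort", class(out))
  out
}

#' Latent truth of a synthetic cohort
#'
#' @param cohort A cohort produced by [generate_cohort()].
#' @return The truth tibble stored alongside the cohort.
#' @export
cohort_truth <- function(cohort) {
  truth <- attr(cohort, "truth")
  if (is.null(truth)) abort("This cohort carries no latent truth attribute.")
  truth
}

# Cause-1 CIF at t for subject-level rates: closed form when both shapes are
# 1, adaptive quadrature otherwise.
cif_closed_form <- function(r, t) {
  if (r$shape1 == 1 && r$shape2 == 1) {
    tot <- r$rate1 + r$rate2
    ifelse(tot == 0, 0, r$rate1 / tot * (1 - exp(-tot * t)))
  } else {
    vapply(seq_along(r$rate1), function(i) {
      if (r$rate1[i] == 0) return(0)
      f <- function(u) {
        r$rate1[i] * r$shape1 * u^(r$shape1 - 1) *
          exp(-r$rate1[i] * u^r$shape1 - r$rate2[i] * u^r$shape2)
      }
      stats::integrate(f, 0, t, rel.tol = 1e-10)$value
    }, 0)
  }
}

#' True cause-1 cumulative incidence under a scenario
#'
#' Closed form for exponential cause-specific hazards,
#' `CIF1(t) = r1/(r1+r2) (1 - exp(-(r1+r2) t))`, and adaptive quadrature of
#' `integral of lambda1(u) exp(-Lambda1(u) - Lambda2(u)) du` for Weibull
#' shapes. The miscalibration knobs are applied exactly as in generation
#' (the top-tail threshold is the configured quantile of the linear
#' predictor over the supplied rows).
#'
#' @param config A [scenario_config()].
#' @param covariates Data frame of covariate rows (must include `age` and
#'   every covariate the hazard models reference).
#' @param t Time in years (>= 0).
#' @return Vector of true cumulative incidences, one per row.
#' @export
true_cumulative_incidence <- function(config, covariates, t) {
  stopifnot(inherits(config, "survalid_scenario"), t >= 0)
  r <- scenario_rates(config, tibble::as_tibble(covariates))
  cif_closed_form(r, t)
}

#' Derive a miscalibrated scenario
#'
#' Returns a copy of the scenario whose generated data, when validated
#' against the UNMODIFIED evaluated model, exhibits the classic external
#' validation failure modes: calibration-slope attenuation of about
#' `1/slope_multiplier`, a mean-calibration ratio of about
#' `baseline_inflation`, and top-decile over-estimation when
#' `top_tail_inflation < 1`.
#'
#' @param config A [scenario_config()].
#' @param slope_multiplier,baseline_inflation,top_tail_inflation Positive
#'   knobs; 1 is the identity.
#' @return A modified `survalid_scenario`.
#' @export
make_miscalibrated_truth <- function(config, slope_multiplier = 1,
                                     baseline_inflation = 1,
                                     top_tail_inflation = 1) {
  stopifnot(inherits(config, "survalid_scenario"))
  for (knob in c(slope_multiplier, baseline_inflation, top_tail_inflation)) {
    if (!is.numeric(knob) || knob <= 0) abort("Miscalibration knobs must be positive.")
  }
  config$slope_multiplier <- slope_multiplier
  config$baseline_inflation <- baseline_inflation
  config$top_tail_inflation <- top_tail_inflation
  config
}

#' Evaluated-model definition matching a scenario's true stroke model
#'
#' Builds the `survalid_model` whose predictions coincide with the
#' scenario's true net (cause-specific) 10-year stroke risk when all
#' miscalibration knobs are 1: identity transforms on the hazard-model
#' covariates, the true coefficients and centring values, and
#' `baseline_survival = exp(-baseline_rate * horizon^shape)`.
#'
#' @param config A [scenario_config()].
#' @param eligibility Optional eligibility predicates to attach.
#' @param name Model name.
#' @return A `survalid_model`.
#' @export
scenario_model <- function(config, eligibility = list(),
                           name = "scenario-true-model") {
  stopifnot(inherits(config, "survalid_scenario"))
  sm <- config$stroke_model
  preds <- lapply(names(sm$coefficients), function(nm) {
    list(name = nm, transform = "identity",
         coefficient = unname(sm$coefficients[[nm]]),
         mean = unname(sm$centring[[nm]]))
  })
  risk_model(
    name = name, outcome_label = "stroke/TIA within horizon",
    horizon = config$horizon,
    baseline_survival = exp(-sm$baseline_rate * config$horizon^sm$shape),
    outcome_fraction = 1, predictors = preds, eligibility = eligibility)
}

#' Write a synthetic cohort (and its truth) to CSV
#'
#' The cohort table and the latent truth go to separate files
#' (`cohort.csv`, `truth.csv`) so a validation run cannot accidentally read
#' the truth channel.
#'
#' @param cohort A `survalid_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cohort_path <- file.path(dir, "cohort.csv")
  truth_path <- file.path(dir, "truth.csv")
  utils::write.csv(as.data.frame(cohort), cohort_path, row.names = FALSE)
  utils::write.csv(as.data.frame(cohort_truth(cohort)), truth_path,
                   row.names = FALSE)
  invisible(c(cohort = cohort_path, truth = truth_path))
}
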