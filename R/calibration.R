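#' Calibration slope
#'
#' The coefficient of the centred prognostic index refit as the single
#' covariate of a Cox proportional-hazards model on the validation data.
#' A slope below 1 indicates predictions that are too extreme (overfitting of
#' the development model); above 1, too compressed. The p-value is a
#' two-sided Wald test of slope = 1.
#'
#' @param data A data frame.
#' @param cpi Column holding the centred prognostic index (tidy-eval).
#' @param time,event Follow-up time and 0/1 event indicator columns (treat
#'   competing deaths as censored for the main variant, or recode them
#'   event-free at the horizon for a competing-risk variant before calling).
#' @return A one-row tibble: `slope`, `std_error`, `conf_low`, `conf_high`,
#'   `p_vs_1`, `n`, `n_events`, `converged`.
#' @export
calibration_slope <- function(data, cpi = cpi, time = time, event = event) {
  fit <- fit_cox_single_covariate(data, {{ cpi }}, {{ time }}, {{ event }})
  z <- (fit$beta - 1) / fit$std_error
  tibble::tibble(
    slope = fit$beta, std_error = fit$std_error,
    conf_low = fit$conf_low, conf_high = fit$conf_high,
    p_vs_1 = 2 * stats::pnorm(-abs(z)),
    n = fit$n, n_events = fit$n_events, converged = fit$converged)
}

#' Mean calibration (calibration-in-the-large)
#'
#' Ratio of the global mean predicted risk to the observed risk at the
#' horizon — Kaplan-Meier failure for the main validation or the cause-1
#' Aalen-Johansen cumulative incidence when accounting for competing deaths.
#' A ratio above 1 indicates global over-estimation; below 1,
#' under-estimation.
#'
#' @param data A data frame.
#' @param prediction Column holding the (outcome-scaled) predicted
#'   probability.
#' @param time,event Follow-up time and 0/1/2 event code columns.
#' @param reference `"km"` or `"cif"`.
#' @param horizon Horizon in years (default 10).
#' @return A one-row tibble: `mean_predicted`, `observed_risk`, `ratio`,
#'   `reference`, `horizon`.
#' @export
mean_calibration <- function(data, prediction, time = time, event = event,
                             reference = c("km", "cif"), horizon = 10) {
  reference <- match.arg(reference)
  p <- dplyr::pull(data, {{ prediction }})
  t <- dplyr::pull(data, {{ time }})
  code <- dplyr::pull(data, {{ event }})
  obs <- observed_risk_core(t, code, horizon, reference)
  if (obs == 0) abort("Observed risk at the horizon is zero; the calibration ratio is undefined.")
  tibble::tibble(
    mean_predicted = mean(p), observed_risk = obs,
    ratio = mean(p) / obs, reference = reference, horizon = horizon)
}

# Near-equal bins over subjects ranked by prediction; ties broken by stable
# input order so the split is deterministic. Sizes differ by at most 1.
prediction_bins <- function(p, n_bins) {
  n <- length(p)
  ord <- order(p) # radix sort: stable in input order on ties
  sizes <- rep(n %/% n_bins, n_bins) + (seq_len(n_bins) <= n %% n_bins)
  bin <- integer(n)
  bin[ord] <- rep(seq_len(n_bins), times = sizes)
  bin
}

#' Decile-based calibration table
#'
#' Ranks subjects by predicted risk, splits them into near-equal bins and
#' compares the mean predicted risk in each bin with the observed risk at the
#' horizon estimated inside the bin (Kaplan-Meier, or cause-1 cumulative
#' incidence under the competing-risk reference).
#'
#' @inheritParams mean_calibration
#' @param n_bins Number of bins (default 10).
#' @return A tibble of class `survalid_decile_table`: `bin`, `n`, `n_events`,
#'   `mean_predicted`, `observed_risk`, `flag_zero_events`, plus `reference`
#'   and `horizon` attributes.
#' @export
decile_calibration <- function(data, prediction, time = time, event = event,
                               n_bins = 10, reference = c("km", "cif"),
                               horizon = 10) {
  reference <- match.arg(reference)
  p <- dplyr::pull(data, {{ prediction }})
  t <- dplyr::pull(data, {{ time }})
  code <- dplyr::pull(data, {{ event }})
  if (length(p) < n_bins) abort("Fewer subjects than bins.")
  bin <- prediction_bins(p, n_bins)
  rows <- lapply(seq_len(n_bins), function(b) {
    sel <- bin == b
    ev <- sum(code[sel] == 1)
    obs <- if (ev == 0) 0 else observed_risk_core(t[sel], code[sel], horizon, reference)
    tibble::tibble(bin = b, n = sum(sel), n_events = ev,
                   mean_predicted = mean(p[sel]), observed_risk = obs,
                   flag_zero_events = ev == 0)
  })
  out <- dplyr::bind_rows(rows)
  if (any(out$flag_zero_events)) {
    warn(paste0("Bin(s) with zero events recorded observed risk 0: ",
                paste(out$bin[out$flag_zero_events], collapse = ", "), "."))
  }
  attr(out, "reference") <- reference
  attr(out, "horizon") <- horizon
  class(out) <- c("survalid_decile_table", class(out))
  out
}

#' Calibration across age groups
#'
#' Per age band: mean predicted risk, Kaplan-Meier observed risk and cause-1
#' cumulative incidence at the horizon. The default bands are <=65,
#' >65-<=70, >70-<=75 and >75 years; the widening gap between the KM and CIF
#' columns across bands displays how strongly competing mortality distorts
#' the naive observed risk in the oldest men.
#'
#' @inheritParams mean_calibration
#' @param age Column holding age in years (default `age`).
#' @param breaks Interior age cut points; bands are `(-Inf, b1]`,
#'   `(b1, b2]`, ..., `(bk, Inf)`.
#' @return A tibble of class `survalid_age_table`: `age_band`, `n`,
#'   `n_events`, `n_competing`, `mean_predicted`, `km_risk`, `cif_risk`.
#' @export
age_group_calibration <- function(data, prediction, age = age, time = time,
                                  event = event, breaks = c(65, 70, 75),
                                  horizon = 10) {
  p <- dplyr::pull(data, {{ prediction }})
  a <- dplyr::pull(data, {{ age }})
  t <- dplyr::pull(data, {{ time }})
  code <- dplyr::pull(data, {{ event }})
  if (anyNA(a)) abort("Ages must not be missing.")
  breaks <- sort(breaks)
  labs <- c(paste0("<=", breaks[1]),
            if (length(breaks) > 1) {
              paste0(">", breaks[-length(breaks)], "-<=", breaks[-1])
            },
            paste0(">", breaks[length(breaks)]))
  band <- cut(a, breaks = c(-Inf, breaks, Inf), labels = labs, right = TRUE)
  empty <- setdiff(labs, unique(as.character(band)))
  if (length(empty) > 0) {
    warn(paste0("Empty age band(s) omitted: ", paste(empty, collapse = ", "), "."))
  }
  rows <- lapply(intersect(labs, unique(as.character(band))), function(l) {
    sel <- as.character(band) == l
    tibble::tibble(
      age_band = l, n = sum(sel), n_events = sum(code[sel] == 1),
      n_competing = sum(code[sel] == 2), mean_predicted = mean(p[sel]),
      km_risk = observed_risk_core(t[sel], code[sel], horizon, "km"),
      cif_risk = observed_risk_core(t[sel], code[sel], horizon, "cif"))
  })
  out <- dplyr::bind_rows(rows)
  out$age_band <- factor(out$age_band, levels = labs)
  class(out) <- c("survalid_age_table", class(out))
  out
}

#' Recode competing deaths as event-free at the horizon
#'
#' The competing-risk adaptation for rank- and regression-based metrics:
#' subjects ending with the competing event are known to be free of the
#' outcome for every horizon, so they are recoded as censored at (beyond) the
#' administrative horizon rather than at their death time.
#'
#' @param data A cohort data frame with 0/1/2 event codes.
#' @param horizon Administrative horizon in years.
#' @return The data with `time`/`event` recoded (event-free subjects carry
#'   `time = horizon`, `event = 0`).
#' @export
recode_competing_as_event_free <- function(data, horizon = 10) {
  data <- as_cohort(data)
  sel <- data$event == 2
  data$time[sel] <- horizon
  data$event[sel] <- 0L
  data
}
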