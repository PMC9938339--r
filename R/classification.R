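#' Censoring-adjusted sensitivity and specificity at a threshold
#'
#' Cumulative/dynamic classification metrics for event-by-horizon status,
#' with the event risk inside each side of the threshold estimated by
#' Kaplan-Meier (main variant) or by the cause-1 Aalen-Johansen cumulative
#' incidence (competing-risk variant), so censored subjects contribute
#' correctly. With `q = P(pred > c)`, `F` the overall risk at the horizon and
#' `F+`/`F-` the risk among subjects above/at-or-below the threshold:
#' `Sn = q F+ / F`, `Sp = (1 - q)(1 - F-) / (1 - F)`, `PPV = F+`,
#' `NPV = 1 - F-`. Estimates are clipped to `[0, 1]` (KM-stratum estimators
#' can stray outside under heavy censoring); clipping is reported.
#' Without censoring or competing events the metrics equal the classical
#' 2x2-table values exactly.
#'
#' @param data A data frame.
#' @param prediction Column holding the predicted probability used for
#'   classification.
#' @param threshold Probability cut-off in (0, 1).
#' @param time,event Follow-up time and 0/1/2 event code columns.
#' @param variant `"main"` (KM) or `"competing_risk"` (CIF).
#' @param horizon Horizon in years (default 10).
#' @param threshold_source Provenance label stored in the result
#'   (`"observed_risk"`, `"clinical"` or `"user"`).
#' @return A one-row tibble of class `survalid_classification`: `threshold`,
#'   `horizon`, `sensitivity`, `specificity`, `ppv`, `npv`, `variant`,
#'   `threshold_source`, `n_above`, `n`, `degenerate`.
#' @export
censoring_adjusted_sn_sp <- function(data, prediction, threshold,
                                     time = time, event = event,
                                     variant = c("main", "competing_risk"),
                                     horizon = 10,
                                     threshold_source = "user") {
  variant <- match.arg(variant)
  p <- dplyr::pull(data, {{ prediction }})
  t <- dplyr::pull(data, {{ time }})
  code <- dplyr::pull(data, {{ event }})
  if (length(threshold) != 1 || threshold < 0 || threshold > 1) {
    abort("`threshold` must be a single probability in [0, 1].")
  }
  if (sum(code == 1) < 1) abort("At least one outcome event is required.")
  reference <- if (variant == "main") "km" else "cif"
  risk_in <- function(sel) {
    if (!any(sel)) return(NA_real_)
    if (sum(code[sel] == 1) == 0) return(0)
    observed_risk_core(t[sel], code[sel], horizon, reference)
  }
  above <- p > threshold
  q <- mean(above)
  f_all <- risk_in(rep(TRUE, length(p)))
  if (f_all <= 0 || f_all >= 1) {
    abort("Overall risk at the horizon is 0 or 1; classification metrics are undefined.")
  }
  f_pos <- risk_in(above)
  f_neg <- risk_in(!above)
  degenerate <- q == 0 || q == 1
  if (degenerate) {
    warn("All predictions fall on one side of the threshold; metrics are degenerate.")
  }
  sn <- if (q == 0) 0 else q * f_pos / f_all
  sp <- if (q == 1) 0 else (1 - q) * (1 - f_neg) / (1 - f_all)
  clipped <- c(sn, sp) < 0 | c(sn, sp) > 1
  if (any(clipped, na.rm = TRUE)) {
    inform("Censoring-adjusted estimate(s) outside [0, 1] were clipped.")
  }
  out <- tibble::tibble(
    threshold = threshold, horizon = horizon,
    sensitivity = min(1, max(0, sn)), specificity = min(1, max(0, sp)),
    ppv = if (is.na(f_pos)) NA_real_ else min(1, max(0, f_pos)),
    npv = if (is.na(f_neg)) NA_real_ else min(1, max(0, 1 - f_neg)),
    variant = variant, threshold_source = threshold_source,
    n_above = sum(above), n = length(p), degenerate = degenerate)
  class(out) <- c("survalid_classification", class(out))
  out
}

#' Classification threshold from the observed risk
#'
#' The overall observed risk at the horizon — Kaplan-Meier failure (main) or
#' cause-1 cumulative incidence (competing-risk variant) — used as the
#' high-risk cut-off for classification.
#'
#' @param data A data frame.
#' @param time,event Follow-up time and 0/1/2 event code columns.
#' @param variant `"main"` or `"competing_risk"`.
#' @param horizon Horizon in years (default 10).
#' @return The threshold as a single number.
#' @export
threshold_at_observed_risk <- function(data, time = time, event = event,
                                       variant = c("main", "competing_risk"),
                                       horizon = 10) {
  variant <- match.arg(variant)
  t <- dplyr::pull(data, {{ time }})
  code <- dplyr::pull(data, {{ event }})
  if (sum(code == 1) < 1) abort("At least one outcome event is required.")
  observed_risk_core(t, code, horizon,
                     if (variant == "main") "km" else "cif")
}

#' Classification at a conventional clinical threshold
#'
#' Applies a composite-CVD intervention threshold — 10% for a QRISK3-type
#' tool, 7.5% for a PCE-type tool, or the threshold a model definition
#' declares — to the UNSCALED composite probabilities, while the outcome
#' being classified remains the stroke event. This is how composite tools
#' are used in practice: the decision is made on composite risk before any
#' correction for stroke outcomes.
#'
#' @param data A data frame.
#' @param prediction_unscaled Column holding the unscaled composite
#'   probability.
#' @param tool `"qrisk3"` (threshold 0.10), `"pce"` (0.075), or `NULL` when
#'   `threshold` is given directly.
#' @param threshold Optional explicit threshold overriding `tool`.
#' @inheritParams censoring_adjusted_sn_sp
#' @return A one-row `survalid_classification` tibble.
#' @export
clinical_threshold_classification <- function(data, prediction_unscaled,
                                              tool = c("qrisk3", "pce"),
                                              threshold = NULL,
                                              time = time, event = event,
                                              variant = c("main", "competing_risk"),
                                              horizon = 10) {
  if (is.null(threshold)) {
    tool <- match.arg(tool)
    threshold <- switch(tool, qrisk3 = 0.10, pce = 0.075)
  }
  censoring_adjusted_sn_sp(
    data, {{ prediction_unscaled }}, threshold, {{ time }}, {{ event }},
    variant = variant, horizon = horizon, threshold_source = "clinical")
}

#' Sweep classification metrics over thresholds
#'
#' One [censoring_adjusted_sn_sp()] row per threshold. Raising the cut-off
#' trades sensitivity for specificity; in an uncensored sample the trade-off
#' is exact and monotone.
#'
#' @inheritParams censoring_adjusted_sn_sp
#' @param thresholds Ascending vector of probability thresholds in (0, 1).
#' @return A tibble with one row per threshold.
#' @export
threshold_sweep <- function(data, prediction, thresholds, time = time,
                            event = event,
                            variant = c("main", "competing_risk"),
                            horizon = 10) {
  variant <- match.arg(variant)
  if (is.unsorted(thresholds)) abort("`thresholds` must be sorted ascending.")
  dplyr::bind_rows(lapply(thresholds, function(th) {
    withCallingHandlers(
      censoring_adjusted_sn_sp(
        data, {{ prediction }}, th, {{ time }}, {{ event }},
        variant = variant, horizon = horizon, threshold_source = "user"),
      warning = function(w) invokeRestart("muffleWarning"))
  }))
}
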