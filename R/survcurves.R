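#' Kaplan-Meier survivor curve
#'
#' Product-limit estimate of the survivor function, computed with
#' [survival::survfit()]. The returned step function is right-continuous and
#' censoring at an event time is processed after the events at that time
#' (the standard convention).
#'
#' @param data A data frame with follow-up times and event indicators.
#' @param time,event Columns holding follow-up time (years, > 0) and the
#'   0/1 event indicator (tidy-eval; default `time` and `event`).
#' @return A tibble of class `survalid_km` with columns `time`, `n_risk`,
#'   `n_event`, `n_censor`, `estimate` (one row per distinct observed time).
#' @export
kaplan_meier <- function(data, time = time, event = event) {
  t <- dplyr::pull(data, {{ time }})
  d <- dplyr::pull(data, {{ event }})
  km_fit(t, d)
}

km_fit <- function(t, d) {
  if (any(t <= 0)) abort("All follow-up times must be strictly positive.")
  if (!all(d %in% c(0, 1))) abort("Event indicator must be 0/1 for a Kaplan-Meier fit.")
  if (sum(d) == 0) {
    warn("No events observed; the Kaplan-Meier curve is flat at 1.")
  }
  fit <- survival::survfit(survival::Surv(t, d) ~ 1)
  out <- tibble::tibble(
    time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
    n_censor = fit$n.censor, estimate = fit$surv)
  class(out) <- c("survalid_km", class(out))
  out
}

#' Risk (1 - survival) at a time point from a Kaplan-Meier curve
#'
#' Right-continuous step lookup; the paper-style "global estimate of failure"
#' used as the observed risk and the high-risk cut-off.
#'
#' @param curve A `survalid_km` curve.
#' @param t Time (years, >= 0).
#' @return `1 - S(t)` as a single number.
#' @export
km_risk_at <- function(curve, t) {
  stopifnot(inherits(curve, "survalid_km"), length(t) == 1, t >= 0)
  if (nrow(curve) == 0 || t < min(curve$time)) return(0)
  if (t > max(curve$time)) {
    warn(sprintf("t = %g is beyond the last observed time %g; returning the last value.",
                 t, max(curve$time)))
  }
  1 - curve$estimate[max(which(curve$time <= t))]
}

#' Aalen-Johansen cumulative incidence under competing risks
#'
#' Multi-state estimate via [survival::survfit()]:
#' `CIF_k(t) = sum_{t_i <= t} S(t_i-) d_{k,i} / n_i` with `S` the all-cause
#' Kaplan-Meier. The per-cause incidences and the overall event-free survival
#' sum to 1 at every time.
#'
#' @param data A data frame with follow-up times and event codes.
#' @param time,event Columns holding follow-up time and the 0/1/2 event code
#'   (0 censored, 1 cause of interest, 2 competing death).
#' @return An object of class `survalid_aj`: a list with `cif` (tibble:
#'   `cause`, `time`, `n_risk`, `n_event`, `estimate`) and `survival`
#'   (a `survalid_km`-shaped tibble of overall event-free survival).
#' @export
aalen_johansen <- function(data, time = time, event = event) {
  t <- dplyr::pull(data, {{ time }})
  code <- dplyr::pull(data, {{ event }})
  aj_fit(t, code)
}

aj_fit <- function(t, code) {
  if (any(t <= 0)) abort("All follow-up times must be strictly positive.")
  if (!all(code %in% c(0, 1, 2))) abort("Event codes must be 0, 1 or 2.")
  state <- factor(code, levels = c(0, 1, 2), labels = c("censor", "1", "2"))
  fit <- survival::survfit(survival::Surv(t, state) ~ 1)
  states <- fit$states
  stopifnot(states[1] == "(s0)")
  cif <- dplyr::bind_rows(lapply(c("1", "2"), function(k) {
    j <- match(k, states)
    tibble::tibble(
      cause = as.integer(k), time = fit$time, n_risk = fit$n.risk[, 1],
      n_event = fit$n.event[, j], estimate = fit$pstate[, j])
  }))
  surv <- tibble::tibble(
    time = fit$time, n_risk = fit$n.risk[, 1],
    n_event = rowSums(fit$n.event[, -1, drop = FALSE]),
    n_censor = rowSums(as.matrix(fit$n.censor)),
    estimate = fit$pstate[, 1])
  class(surv) <- c("survalid_km", class(surv))
  structure(list(cif = cif, survival = surv), class = "survalid_aj")
}

#' @export
print.survalid_aj <- function(x, ...) {
  cat("<survalid_aj> Aalen-Johansen estimate,",
      length(unique(x$cif$time)), "time points\n")
  for (k in unique(x$cif$cause)) {
    sub <- x$cif[x$cif$cause == k, ]
    cat(sprintf("  cause %d: CIF(last) = %.4f over %d events\n",
                k, sub$estimate[nrow(sub)], sum(sub$n_event)))
  }
  invisible(x)
}

#' Cumulative incidence at a time point
#'
#' @param aj A `survalid_aj` object.
#' @param t Time (years, >= 0).
#' @param cause Cause code (1 outcome, 2 competing death).
#' @return `CIF_cause(t)` by right-continuous lookup.
#' @export
cif_risk_at <- function(aj, t, cause = 1) {
  stopifnot(inherits(aj, "survalid_aj"), length(t) == 1, t >= 0)
  sub <- aj$cif[aj$cif$cause == cause, ]
  if (nrow(sub) == 0 || t < min(sub$time)) return(0)
  if (t > max(sub$time)) {
    warn(sprintf("t = %g is beyond the last observed time %g; returning the last value.",
                 t, max(sub$time)))
  }
  sub$estimate[max(which(sub$time <= t))]
}

# Observed risk at a horizon: KM (competing deaths censored) or cause-1 CIF.
observed_risk_core <- function(t, code, horizon, reference = c("km", "cif")) {
  reference <- match.arg(reference)
  if (reference == "km") {
    km_risk_at(km_fit(t, as.integer(code == 1)), horizon)
  } else {
    cif_risk_at(aj_fit(t, code), horizon, cause = 1)
  }
}
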