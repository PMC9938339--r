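#' Harrell's C-index for censored survival data
#'
#' A pair is comparable iff the smaller observed time belongs to an event;
#' it is concordant when the subject failing earlier carries the higher
#' prediction, and tied predictions count one half. Tied event times carry no
#' ordering information; an event tied with a censoring time is compared with
#' the event treated as earlier. The standard error is a leave-one-out
#' jackknife over subjects.
#'
#' @param data A data frame.
#' @param prediction Column holding the risk prediction (any monotone score:
#'   PI, CPI or predicted probability give identical C).
#' @param time,event Follow-up time and event columns. For
#'   `harrells_c()` the event column must be 0/1 (code 2, if present, is an
#'   error); for `harrells_c_competing()` it holds 0/1/2 codes and subjects
#'   ending with the competing event are recoded as event-free beyond every
#'   observed time before the standard pair rule applies.
#' @return A one-row tibble of class `survalid_cindex`: `c_index`,
#'   `std_error`, `conf_low`, `conf_high` (clipped to `[0, 1]`), `n_pairs`,
#'   `n`, `n_events`, `variant`.
#' @export
harrells_c <- function(data, prediction, time = time, event = event) {
  p <- dplyr::pull(data, {{ prediction }})
  t <- dplyr::pull(data, {{ time }})
  d <- dplyr::pull(data, {{ event }})
  if (!all(d %in% c(0, 1))) {
    abort("`event` must be 0/1 for harrells_c(); use harrells_c_competing() for 0/1/2 codes.")
  }
  cindex_core(t, d, p, variant = "main")
}

#' @rdname harrells_c
#' @export
harrells_c_competing <- function(data, prediction, time = time, event = event) {
  p <- dplyr::pull(data, {{ prediction }})
  t <- dplyr::pull(data, {{ time }})
  code <- dplyr::pull(data, {{ event }})
  if (!all(code %in% c(0, 1, 2))) abort("Event codes must be 0, 1 or 2.")
  rec <- recode_competing_event_free(t, code)
  cindex_core(rec$time, rec$event, p, variant = "competing_risk")
}

# Competing-death subjects are known event-free for every horizon: push their
# comparison time beyond all observed times and censor them there.
recode_competing_event_free <- function(t, code) {
  t2 <- t
  t2[code == 2] <- max(t) + 1
  list(time = t2, event = as.integer(code == 1))
}

cindex_core <- function(t, d, p, variant) {
  if (any(t <= 0)) abort("All follow-up times must be strictly positive.")
  if (sum(d) < 1) abort("At least one event is required for the C-index.")
  if (anyNA(p)) abort("Predictions must not be missing.")
  cc <- concordance_counts(as.numeric(t), as.integer(d), as.numeric(p))
  if (cc$comparable == 0) {
    abort("No comparable pairs; the C-index is undefined for these data.")
  }
  score <- cc$concordant + 0.5 * cc$tied
  c_hat <- score / cc$comparable
  # leave-one-out: subtract subject i's pair contributions
  score_i <- cc$concordant_i + 0.5 * cc$tied_i
  denom_i <- cc$comparable - cc$comparable_i
  ok <- denom_i > 0
  c_loo <- (score - score_i[ok]) / denom_i[ok]
  m <- length(c_loo)
  se <- if (m > 1) {
    sqrt((m - 1) / m * sum((c_loo - mean(c_loo))^2))
  } else {
    NA_real_
  }
  out <- tibble::tibble(
    c_index = c_hat, std_error = se,
    conf_low = max(0, c_hat - stats::qnorm(0.975) * se),
    conf_high = min(1, c_hat + stats::qnorm(0.975) * se),
    n_pairs = cc$comparable, n = length(t), n_events = sum(d),
    variant = variant)
  class(out) <- c("survalid_cindex", class(out))
  out
}

#' Risk groups from centiles of the prognostic index
#'
#' Assigns four risk groups cut at the 16th, 50th and 84th centiles of the
#' sample's prognostic index (linear-interpolation quantiles). Groups are the
#' half-open intervals `[lo, hi)` with the top group closed; group sizes
#' approximate 16/34/34/16% up to ties.
#'
#' @param data A data frame.
#' @param pi Column holding the prognostic index (tidy-eval; default `pi`).
#' @return `data` with an added factor column `risk_group` (levels `low`,
#'   `intermediate`, `high`, `very_high`) and a `cut_points` attribute.
#' @export
risk_groups_by_pi <- function(data, pi = pi) {
  v <- dplyr::pull(data, {{ pi }})
  if (length(v) < 4) abort("At least 4 subjects are needed to form risk groups.")
  cuts <- stats::quantile(v, c(0.16, 0.50, 0.84), names = FALSE, type = 7)
  if (anyDuplicated(cuts)) {
    warn("Tied centile cut points collapse one or more risk groups; grouping will be unbalanced.")
  }
  labels <- c("low", "intermediate", "high", "very_high")
  idx <- findInterval(v, cuts, left.open = FALSE) # [lo, hi): x < cut stays below
  grp <- factor(labels[idx + 1], levels = labels)
  out <- dplyr::mutate(tibble::as_tibble(data), risk_group = grp)
  attr(out, "cut_points") <- stats::setNames(cuts, c("p16", "p50", "p84"))
  out
}

#' Kaplan-Meier curves per risk group
#'
#' One product-limit curve per risk group, stacked into a tidy table for the
#' classic separation display. Empty groups are omitted with a warning.
#'
#' @param data A data frame containing a grouping column (e.g. the output of
#'   [risk_groups_by_pi()]).
#' @param group Grouping column (tidy-eval; default `risk_group`).
#' @param time,event Follow-up time and 0/1 event indicator columns.
#' @return A tibble of class `survalid_km_groups`: `group`, `time`, `n_risk`,
#'   `n_event`, `n_censor`, `estimate`.
#' @export
km_by_group <- function(data, group = risk_group, time = time, event = event) {
  data <- tibble::as_tibble(data)
  g <- dplyr::pull(data, {{ group }})
  t <- dplyr::pull(data, {{ time }})
  d <- dplyr::pull(data, {{ event }})
  levs <- if (is.factor(g)) levels(g) else sort(unique(g))
  empty <- setdiff(levs, unique(as.character(g)))
  if (length(empty) > 0) {
    warn(paste0("Empty group(s) omitted: ", paste(empty, collapse = ", "), "."))
  }
  out <- dplyr::bind_rows(lapply(intersect(levs, unique(as.character(g))), function(l) {
    sel <- as.character(g) == l
    dplyr::mutate(km_fit(t[sel], d[sel]), group = l, .before = 1)
  }))
  out$group <- factor(out$group, levels = levs)
  class(out) <- c("survalid_km_groups", class(out))
  out
}
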