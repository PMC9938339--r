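#' Validate a subject-level cohort table
#'
#' Checks the minimal contract every validation function relies on: columns
#' `id`, `time` (years, strictly positive), `event` (0 censored, 1 outcome,
#' 2 competing non-outcome death) and `age`. Any remaining columns are
#' treated as covariates for the risk model being validated.
#'
#' @param data A data frame with one row per subject.
#' @return The cohort as a tibble, invisibly validated.
#' @export
as_cohort <- function(data) {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  needed <- c("id", "time", "event", "age")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Cohort is missing required column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  data <- tibble::as_tibble(data)
  if (!is.numeric(data$time) || anyNA(data$time) || any(data$time <= 0)) {
    abort("`time` must be numeric, non-missing and strictly positive.")
  }
  if (anyNA(data$event) || !all(data$event %in% c(0L, 1L, 2L))) {
    abort("`event` codes must all be 0 (censored), 1 (outcome) or 2 (competing death).")
  }
  data$event <- as.integer(data$event)
  data
}

#' Read a cohort CSV
#'
#' Expects a header row with at least `id`, `time`, `event`, `age`; other
#' columns are carried along as covariates. Empty cells become missing values.
#'
#' @param path Path to a CSV file.
#' @return A validated cohort tibble.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) abort(paste0("Cohort file not found: ", path))
  if (requireNamespace("readr", quietly = TRUE)) {
    data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    data <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  as_cohort(data)
}

#' Cap follow-up at an administrative horizon
#'
#' Subjects whose follow-up exceeds the horizon are administratively censored
#' at the horizon: their time is set to the horizon and their event code to 0.
#' Events recorded beyond the horizon are outside the prediction window of a
#' horizon-limited validation and do not count.
#'
#' @param data A cohort data frame.
#' @param horizon Horizon in years (default 10).
#' @return The cohort with follow-up capped, as a tibble.
#' @export
cap_horizon <- function(data, horizon = 10) {
  data <- as_cohort(data)
  over <- data$time > horizon
  if (any(over)) {
    data$event[over] <- 0L
    data$time[over] <- horizon
  }
  data
}
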