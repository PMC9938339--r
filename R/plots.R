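#' Calibration plot for a decile table
#'
#' Observed versus mean predicted risk per bin with the 45-degree perfect
#' calibration reference.
#'
#' @param object A `survalid_decile_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.survalid_decile_table <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$mean_predicted,
                               y = .data$observed_risk)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "Mean predicted risk", y = "Observed risk",
      title = sprintf("Calibration in %d bins (%s reference, %gy horizon)",
                      nrow(object), attr(object, "reference") %||% "km",
                      attr(object, "horizon") %||% 10)) +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier separation plot for risk groups
#'
#' @param object A `survalid_km_groups` table from [km_by_group()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.survalid_km_groups <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$time, y = .data$estimate,
                               colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Years", y = "Event-free survival",
                  colour = "Risk group",
                  title = "Survival by prognostic-index risk group") +
    ggplot2::theme_minimal()
}

#' Age-band calibration plot
#'
#' Mean predicted risk against the Kaplan-Meier and cumulative-incidence
#' observed risks per age band; the widening KM-CIF gap with age displays
#' the growing influence of competing mortality.
#'
#' @param object A `survalid_age_table` from [age_group_calibration()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.survalid_age_table <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    c("mean_predicted", "km_risk", "cif_risk"),
    names_to = "quantity", values_to = "risk")
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$age_band, y = .data$risk,
                               group = .data$quantity,
                               colour = .data$quantity)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Age band (years)", y = "10-year risk",
                  colour = NULL, title = "Calibration across age groups") +
    ggplot2::theme_minimal()
}
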