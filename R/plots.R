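#' Plot an expression profile
#'
#' Line plot of predicted transcription rate against anterior-posterior
#' position, one panel or color per construct.
#'
#' @param object An `expression_profile` tibble from [predict_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.expression_profile <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$position, y = .data$rate,
                               color = .data$construct)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "A-P position (% egg length)",
                  y = "transcription rate", color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a per-site activation dissection map
#'
#' Heatmap of per-binding-site contributions to the summed activation
#' (\eqn{\Delta E_i = \alpha_i f^{AQ}_i}) over anterior-posterior position
#' (y) and bp 5' of the TSS (x), the standard view for attributing
#' expression features to individual sites.
#'
#' @param object A `dissection_map` from [dissect()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.dissection_map <- function(object, ...) {
  ggplot2::ggplot(object$grid,
                  ggplot2::aes(x = .data$bp_5prime_of_tss,
                               y = .data$position,
                               fill = .data$delta_E)) +
    ggplot2::geom_tile(width = 14) +
    ggplot2::scale_x_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "bp 5' of TSS", y = "A-P position (% egg length)",
                  fill = expression(Delta * E),
                  title = object$construct) +
    ggplot2::theme_minimal()
}

#' Plot the objective trace of a fit
#'
#' @param object A `thermo_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.thermo_fit <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = .data$eval, y = .data$best_ssq)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "objective evaluations", y = "best sum of squares") +
    ggplot2::theme_minimal()
}

#' Plot TF concentration profiles
#'
#' @param profiles A profile tibble (`position` plus one column per TF).
#' @return A ggplot object.
#' @export
plot_profiles <- function(profiles) {
  long <- tidyr::pivot_longer(profiles, -"position",
                              names_to = "tf", values_to = "level")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$position, y = .data$level,
                                     color = .data$tf)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "A-P position (% egg length)",
                  y = "relative fluorescence", color = NULL) +
    ggplot2::theme_minimal()
}
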