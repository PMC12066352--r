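#' Plot a temperature trajectory
#'
#' Point estimates of network temperature per age with analytic
#' (and, when present, bootstrap) 95\% interval bars. A minimal
#' error-bar display; restyle with further ggplot2 layers as needed.
#'
#' @param object A `temp_trajectory` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot temp_trajectory
#' @export
autoplot.temp_trajectory <- function(object, ...) {
  gg <- ggplot2::ggplot(object, ggplot2::aes(x = .data$age,
                                             y = .data$temperature)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lo,
                                        ymax = .data$ci_hi),
                           width = 0.15, colour = "#6a51a3") +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 2)
  if (any(is.finite(object$boot_lo))) {
    gg <- gg + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$boot_lo, ymax = .data$boot_hi),
      width = 0.3, colour = "#e6a700", linetype = 2
    )
  }
  gg + ggplot2::labs(x = "Age (years)",
                     y = "Network temperature (T, wave 1 = 1)") +
    ggplot2::theme_minimal()
}

#' @export
plot.temp_trajectory <- function(x, ...) print(autoplot.temp_trajectory(x, ...))

#' Plot a model-selection table
#'
#' BIC per model, faceted nothing, dense/sparse dodged; the chosen model
#' is highlighted.
#'
#' @param object An `mg_selection`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mg_selection
#' @export
autoplot.mg_selection <- function(object, ...) {
  tb <- object$table
  tb$model <- factor(tb$model, levels = unique(tb$model))
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$model, y = .data$bic,
                                   fill = .data$structure,
                                   alpha = .data$chosen)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_alpha_manual(values = c(`FALSE` = 0.45, `TRUE` = 1),
                                guide = "none") +
    ggplot2::labs(x = NULL, y = "BIC") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot stratified trajectories
#'
#' Relative cooling curves per stratum; the y axis is relative to each
#' stratum's own first occasion, not an absolute temperature.
#'
#' @param object A `stratified_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot stratified_fit
#' @export
autoplot.stratified_fit <- function(object, ...) {
  rows <- purrr::imap_dfr(object$trajectories, function(tr, s) {
    dplyr::mutate(tr, stratum = s)
  })
  ggplot2::ggplot(rows, ggplot2::aes(x = .data$age, y = .data$temperature,
                                     colour = .data$stratum)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lo,
                                        ymax = .data$ci_hi), width = 0.15) +
    ggplot2::labs(x = "Age (years)",
                  y = "Relative network temperature (each stratum anchored at 1)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
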