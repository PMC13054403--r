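#' Group-mean saliva trajectories
#'
#' Mean value per group and timepoint with standard-error ribbons, the
#' standard cortisol (or subjective stress) time-course display.
#'
#' @param series Long tibble (`participant_id`, `timepoint`, `minutes`,
#'   `value`).
#' @param covariates Tibble mapping `participant_id` to `group`.
#' @param ylab Axis label.
#' @return A ggplot object.
#' @export
plot_trajectories <- function(series, covariates,
                              ylab = "salivary cortisol (nmol/L)") {
  d <- series %>%
    left_join(select(covariates, "participant_id", "group"),
              by = "participant_id") %>%
    group_by(.data$group, .data$timepoint, .data$minutes) %>%
    summarise(mean = mean(.data$value, na.rm = TRUE),
              sem = sd(.data$value, na.rm = TRUE) / sqrt(sum(!is.na(.data$value))),
              .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$minutes, y = .data$mean,
                                  colour = .data$group, fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "minutes relative to stress induction (T2)", y = ylab,
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Distribution of inferred SCFA producer capacity
#'
#' @param capacities Long capacity tibble (see [capacity_score()]).
#' @return A ggplot object.
#' @export
plot_capacity <- function(capacities) {
  ggplot2::ggplot(capacities,
                  ggplot2::aes(x = .data$capacity, fill = .data$scfa)) +
    ggplot2::geom_histogram(bins = 30, alpha = 0.7, position = "identity") +
    ggplot2::labs(x = "summed producer relative abundance", y = "samples",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Diagnostic plot for a Huber fit
#'
#' Residuals against fitted values with points shaded by their final IRLS
#' weight, making the downweighted observations visible at a glance.
#'
#' @param object A [fit_huber()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.huber_fit <- function(object, ...) {
  d <- tibble(fitted = object$fitted, residual = object$residuals,
              weight = object$weights)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$fitted, y = .data$residual,
                                  colour = .data$weight)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::scale_colour_gradient(limits = c(0, 1), low = "red", high = "black") +
    ggplot2::labs(x = "fitted value", y = "residual", colour = "Huber weight") +
    ggplot2::theme_minimal()
}
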