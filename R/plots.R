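#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bar chart of mean cross-validated accuracy per model and representation
#'
#' Mirrors the usual comparative-accuracy figure: one bar per model and
#' input representation with error bars of one fold standard deviation.
#'
#' @param object A `cv_report` from [compare_models()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cv_report <- function(object, ...) {
  summary <- object$folds |>
    dplyr::group_by(.data$model, .data$representation) |>
    dplyr::summarise(
      mean_acc = mean(.data$accuracy),
      std = stats::sd(.data$accuracy),
      .groups = "drop"
    )
  ggplot2::ggplot(
    summary,
    ggplot2::aes(
      x = .data$model, y = .data$mean_acc, fill = .data$representation
    )
  ) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$mean_acc - .data$std,
        ymax = .data$mean_acc + .data$std
      ),
      position = ggplot2::position_dodge(width = 0.8), width = 0.2
    ) +
    ggplot2::labs(
      x = NULL, y = "Mean CV accuracy", fill = "Input",
      title = "Kinematics features vs raw vital signs"
    ) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' Calibration (reliability) curves per model and representation
#'
#' @param report A `cv_report` from [compare_models()].
#' @return A ggplot object with one panel per model, the diagonal as
#'   reference.
#' @export
plot_calibration <- function(report) {
  stopifnot(inherits(report, "cv_report"))
  ggplot2::ggplot(
    report$calibration,
    ggplot2::aes(
      x = .data$mean_pred, y = .data$frac_pos,
      colour = .data$representation
    )
  ) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~model) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Mean predicted probability",
      y = "Observed positive fraction",
      colour = "Input"
    ) +
    ggplot2::theme_minimal()
}

#' Distance-to-sepsis-position trajectories
#'
#' Plots each patient's hourly Euclidean distance to the sepsis position,
#' coloured by outcome — the geometric picture behind the kinematics
#' features: positives close in on the point, negatives do not.
#'
#' @param cohort Preprocessed cohort tibble.
#' @param position A `sepsis_position`.
#' @param alpha Line transparency.
#' @return A ggplot object.
#' @export
plot_distance_trajectories <- function(cohort, position, alpha = 0.3) {
  rk <- relative_kinematics(cohort, position)
  ggplot2::ggplot(
    rk,
    ggplot2::aes(
      x = .data$hour, y = .data$dist, group = .data$patient_id,
      colour = factor(.data$label, c(0, 1), c("negative", "positive"))
    )
  ) +
    ggplot2::geom_line(alpha = alpha) +
    ggplot2::labs(
      x = "Window hour", y = "Distance to sepsis position",
      colour = "Outcome"
    ) +
    ggplot2::theme_minimal()
}
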