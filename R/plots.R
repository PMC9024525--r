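# ggplot2 views of traces, training histories and evaluation reports.

#' Plot a motion trace
#'
#' Shows the AP chest-wall channel (and the tumor displacement when
#' present) against time, with detected or ground-truth cycle starts marked.
#'
#' @param object A `motion_trace`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot motion_trace
#' @export
autoplot.motion_trace <- function(object, ...) {
  df <- tibble::as_tibble(object)
  long <- df |>
    dplyr::select(dplyr::any_of(c("time_s", "marker_y_mm", "tumor_disp_mm"))) |>
    tidyr::pivot_longer(-"time_s", names_to = "channel", values_to = "mm")
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$time_s, .data$mm,
                                          colour = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "displacement (mm)", colour = NULL) +
    ggplot2::theme_minimal()
  cs <- attr(object, "cycle_starts")
  if (!is.null(cs)) {
    p <- p + ggplot2::geom_vline(
      xintercept = df$time_s[cs], linetype = "dotted", colour = "grey50"
    )
  }
  p
}

#' Plot a training history
#'
#' Train and test loss per epoch with the best (returned) epoch marked.
#'
#' @param object A `tsnet_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot tsnet_fit
#' @export
autoplot.tsnet_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history, -"epoch",
                              names_to = "partition", values_to = "loss")
  ggplot2::ggplot(long, ggplot2::aes(.data$epoch, .data$loss,
                                     colour = .data$partition)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dashed") +
    ggplot2::labs(
      title = sprintf("%s head, best epoch %d", object$head, object$best_epoch),
      x = "epoch", y = "loss", colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-phase F1 scores
#'
#' @param object A `classification_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot classification_report
#' @export
autoplot.classification_report <- function(object, ...) {
  ggplot2::ggplot(object$table, ggplot2::aes(factor(.data$phase), .data$f1)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::labs(
      title = sprintf("Total accuracy %.2f%%", object$total_accuracy),
      x = "respiratory phase (x10%)", y = "F1 score (%)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot predicted vs actual tumor displacement
#'
#' @param object A `regression_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot regression_report
#' @export
autoplot.regression_report <- function(object, ...) {
  df <- object$data
  use_mm <- !all(is.na(df$truth_mm))
  x <- if (use_mm) df$truth_mm else df$truth_norm
  y <- if (use_mm) df$pred_mm else df$pred_norm
  unit <- if (use_mm) "mm" else "(normalized)"
  ggplot2::ggplot(tibble::tibble(actual = x, predicted = y),
                  ggplot2::aes(.data$actual, .data$predicted)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(
      title = sprintf("R² = %.3f", object$r2),
      x = paste("actual displacement", unit),
      y = paste("predicted displacement", unit)
    ) +
    ggplot2::theme_minimal()
}
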