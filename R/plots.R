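#' Plot an evaluation report
#'
#' `type = "scatter"` draws predicted versus observed release with the
#' identity line; `type = "residuals"` draws residuals (predicted minus
#' observed) against the observed values with a zero reference line.
#'
#' @param object An `eval_report`.
#' @param type `"scatter"` or `"residuals"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eval_report <- function(object, type = c("scatter", "residuals"), ...) {
  type <- match.arg(type)
  df <- object$predictions
  if (type == "scatter") {
    ggplot2::ggplot(df, ggplot2::aes(.data$observed, .data$predicted,
                                     colour = factor(.data$ph))) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
      ggplot2::geom_point(alpha = 0.8) +
      ggplot2::labs(x = "Observed Q (%)", y = "Predicted Q (%)",
                    colour = "pH",
                    title = sprintf("%s: R² = %.2f, RMSE = %.1f%%",
                                    object$variant, object$r_squared,
                                    object$rmse)) +
      ggplot2::coord_equal(xlim = c(0, 100), ylim = c(0, 100)) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(df, ggplot2::aes(.data$observed, .data$residual,
                                     colour = factor(.data$ph))) +
      ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
      ggplot2::geom_point(alpha = 0.8) +
      ggplot2::labs(x = "Observed Q (%)", y = "Predicted - observed (%)",
                    colour = "pH") +
      ggplot2::theme_minimal()
  }
}

#' Plot a dissolution profile
#'
#' Observed and model-reconstructed release over time for one experiment.
#'
#' @param object A `dissolution_profile` from [reconstruct_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dissolution_profile <- function(object, ...) {
  long <- tidyr_pivot(object)
  ggplot2::ggplot(long, ggplot2::aes(.data$time_min, .data$q,
                                     colour = .data$source)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Time (min)", y = "Q (%)",
                  title = sprintf("%s, pH %s", object$formulation_id[1],
                                  object$ph[1])) +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}

# minimal long-format reshape (observed/predicted)
tidyr_pivot <- function(profile) {
  dplyr::bind_rows(
    tibble::tibble(time_min = profile$time_min, q = profile$q_observed,
                   source = "observed"),
    tibble::tibble(time_min = profile$time_min, q = profile$q_predicted,
                   source = "predicted"))
}

#' Plot a saliency map
#'
#' Heatmap of the Grad-CAM importance field.
#'
#' @param object A `saliency_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.saliency_map <- function(object, ...) {
  h <- object$heatmap
  df <- expand.grid(row = seq_len(nrow(h)), col = seq_len(ncol(h)))
  df$importance <- as.vector(h)
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$importance)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("Grad-CAM, %s nm branch", object$branch),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
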