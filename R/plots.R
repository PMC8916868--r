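image_df <- function(m) {
  tibble::tibble(
    row = rep(seq_len(nrow(m)), times = ncol(m)),
    col = rep(seq_len(ncol(m)), each = nrow(m)),
    value = as.vector(m))
}

#' Plot a noise-level sweep
#'
#' One panel per quality metric, noise standard deviation on the x axis,
#' one line per method.
#'
#' @param object A `noise_sweep` tibble from [sweep_noise_levels()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot noise_sweep
#' @export
autoplot.noise_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("mse", "psnr", "ssim"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sigma, y = .data$value,
                                     colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "noise standard deviation", y = NULL,
                  colour = "method") +
    ggplot2::theme_minimal()
}

#' Plot a ROC curve
#'
#' @param object A `diag_result` from [diagnostic_eval()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot diag_result
#' @export
autoplot.diag_result <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}

#' Plot a B-mode skin phantom
#'
#' @param object A `skin_phantom` from [make_skin_phantom()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot skin_phantom
#' @export
autoplot.skin_phantom <- function(object, ...) {
  df <- image_df(object$image)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = "depth (px)", fill = "intensity") +
    ggplot2::theme_minimal()
}

#' Plot an elasticity phantom with its lesion outline
#'
#' @param object An `elasticity_phantom` from [make_elasticity_phantom()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot elasticity_phantom
#' @export
autoplot.elasticity_phantom <- function(object, ...) {
  df <- image_df(object$map)
  df$lesion <- as.vector(object$mask)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::geom_contour(ggplot2::aes(z = as.numeric(.data$lesion)),
                          breaks = 0.5, colour = "white", linewidth = 0.3) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(option = "inferno") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "E (kPa)") +
    ggplot2::theme_minimal()
}
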