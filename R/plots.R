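#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
generics::tidy

#' @export
generics::glance

#' Bland-Altman plot
#'
#' Mean of each pair on the x-axis, difference on the y-axis; the solid line
#' is the bias and the dashed lines the limits of agreement (bias +/- 1.96
#' standard deviations of the differences).
#'
#' @param object A [bland_altman()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$mean, y = .data$difference)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$bias, linewidth = 0.7) +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed") +
    ggplot2::labs(x = "Mean of paired measurements",
                  y = "Difference (y - x)",
                  title = sprintf("Bland-Altman (n = %d)", object$n)) +
    ggplot2::theme_minimal()
}

#' @export
tidy.bland_altman <- function(x, ...) x$data

#' @export
glance.bland_altman <- function(x, ...) {
  tibble::tibble(bias = x$bias, sd = x$sd, loa_low = x$loa_low,
                 loa_high = x$loa_high, n = x$n)
}

#' Training curve
#'
#' Per-epoch loss with learning-rate drops marked.
#'
#' @param object A `patmc_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.patmc_fit <- function(object, ...) {
  drops <- object$log$epoch[c(FALSE, diff(object$log$lr) < 0)]
  ggplot2::ggplot(object$log, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = drops, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = object$best_epoch, colour = "steelblue") +
    ggplot2::labs(x = "Epoch", y = "Training loss (BCE)",
                  title = "Training curve (dotted: LR drops; blue: best epoch)") +
    ggplot2::theme_minimal()
}

#' Quality-control calibration plot
#'
#' Raw mean pairwise Dice (d^MC) against true Dice with the fitted linear
#' correction and the identity line.
#'
#' @param object A `qc_calibration` fitted with data attached.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.qc_calibration <- function(object, ...) {
  assert_that(!is.null(object$data), "calibration carries no fit data")
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$d_mc, y = .data$true_dice)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(x = "Mean pairwise Dice of MC samples (d^MC)",
                  y = "True Dice of consensus",
                  title = sprintf("QC calibration: %.2f + %.2f d^MC (r = %.2f)",
                                  object$intercept, object$slope, object$fit_r)) +
    ggplot2::theme_minimal()
}

#' Overlay an image with a mask
#'
#' Quick-look raster of a grayscale frame with a segmentation outline.
#'
#' @param img A [grayscale_image()].
#' @param mask Optional [binary_mask()] of the same shape.
#' @return A ggplot.
#' @export
plot_segmentation <- function(img, mask = NULL) {
  img <- as_image(img)
  df <- tidyr::expand_grid(row = seq_len(nrow(img$pixels)),
                           col = seq_len(ncol(img$pixels)))
  df$intensity <- as.vector(img$pixels)  # expand_grid varies col fastest
  df$intensity <- img$pixels[cbind(df$row, df$col)]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (!is.null(mask)) {
    mask <- as_mask(mask)
    b <- which_boundary_px(mask$pixels)
    if (nrow(b) > 0) {
      p <- p + ggplot2::geom_point(
        data = tibble::tibble(row = b[, 1], col = b[, 2]),
        colour = "orange", size = 0.3)
    }
  }
  p
}
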